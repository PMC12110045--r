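#' Load a rate-distortion problem from disk
#'
#' Accepts either a JSON file with fields `q` (vector) and `d` (matrix,
#' rows = outputs, cols = inputs), or a pair of delimited-text files
#' (`path` = the `q` file, `d_path` = the matrix file, whitespace- or
#' tab-separated).  All construction invariants are validated on load with
#' field-level messages.
#'
#' @param path path to a JSON problem file, or to the `q` text file.
#' @param d_path optional path to the distortion-matrix text file.
#' @return An [rd_problem()].
#' @export
load_problem <- function(path, d_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(d_path)) {
    obj <- tryCatch(jsonlite::fromJSON(path),
                    error = function(e) stop("malformed JSON in ", path,
                                             ": ", conditionMessage(e)))
    if (is.null(obj$q)) stop("field `q` missing in ", path)
    if (is.null(obj$d)) stop("field `d` missing in ", path)
    q <- as.numeric(obj$q)
    d <- obj$d
    if (!is.matrix(d)) d <- do.call(rbind, d)
  } else {
    q <- scan(path, quiet = TRUE)
    d <- as.matrix(utils::read.table(d_path))
  }
  if (!is.numeric(d) || nrow(d) != length(q) || ncol(d) != length(q))
    stop("field `d` must be a square matrix matching length(q) = ",
         length(q), " (got ", nrow(d), "x", ncol(d), ")")
  rd_problem(q, d)
}

#' Write a problem to JSON
#'
#' @param problem an [rd_problem()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_problem <- function(problem, path) {
  stopifnot(inherits(problem, "rd_problem"))
  jsonlite::write_json(list(q = problem$q, d = problem$d), path,
                       digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' Write a rate-distortion curve as delimited text plus JSON sidecar
#'
#' Writes `<stem>.tsv` with columns `beta`, `w`, `D`, `R`, `n_support`
#' (header line documents the codebook convention rows = outputs,
#' cols = inputs) and `<stem>.json` carrying per-point support sets and,
#' optionally, the codebooks.
#'
#' @param curve an [rd_curve()].
#' @param stem output path stem (no extension).
#' @param codebooks logical; include full codebooks in the sidecar.
#' @return The TSV path, invisibly.
#' @export
write_rd_curve <- function(curve, stem, codebooks = FALSE) {
  stopifnot(inherits(curve, "rd_curve"))
  tsv <- paste0(stem, ".tsv")
  con <- file(tsv, "w")
  writeLines("# rate-distortion curve; codebook convention: rows=outputs, cols=inputs", con)
  utils::write.table(format(curve_points(curve), digits = 17, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  side <- list(beta = curve$beta,
               D = vapply(curve$solutions, `[[`, numeric(1), "D"),
               R = vapply(curve$solutions, `[[`, numeric(1), "R"),
               support = lapply(curve$solutions, `[[`, "support"))
  if (codebooks)
    side$codebook <- lapply(curve$solutions, `[[`, "codebook")
  jsonlite::write_json(side, paste0(stem, ".json"), digits = NA)
  invisible(tsv)
}

#' Write / read a divergence series as delimited text
#'
#' Columns `t_mid`, `M_raw`, `M_norm`, full double precision.
#'
#' @param series a [divergence_series()].
#' @param path output path.
#' @return `path` invisibly (write); a `divergence_series` (read).
#' @export
write_divergence_series <- function(series, path) {
  stopifnot(inherits(series, "divergence_series"))
  df <- data.frame(t_mid = series$t_mid, M_raw = series$M_raw,
                   M_norm = series$M_norm)
  utils::write.table(format(df, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_divergence_series
#' @export
read_divergence_series <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  structure(list(t_mid = df$t_mid, M_raw = df$M_raw, M_norm = df$M_norm,
                 q = NULL, constant = all(df$M_raw == df$M_raw[1])),
            class = "divergence_series")
}

#' Read grayscale images from files
#'
#' Reads PNG files (via the `png` package) or plain-text matrices
#' (whitespace-delimited, one row per line) into numeric matrices in
#' `[0, 1]`.  Color PNGs are averaged across channels.
#'
#' @param paths character vector of file paths.
#' @return A list of numeric matrices.
#' @export
load_images <- function(paths) {
  lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    if (grepl("\\.png$", p, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the `png` package")
      img <- png::readPNG(p)
      if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
      img
    } else {
      as.matrix(utils::read.table(p))
    }
  })
}
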