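#' Write / read an AFM height image as plain text
#'
#' Height maps are stored as a tab-separated numeric matrix with a JSON
#' sidecar (`<path>.json`) carrying the physical pixel size, dimensions
#' and provenance id. (A plain-text container is used so datasets remain
#' diffable and portable; the sidecar plays the role TIFF resolution tags
#' would.)
#'
#' @param image an `afm_image`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_afm_image <- function(image, path) {
  stopifnot(inherits(image, "afm_image"))
  utils::write.table(image$heights, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(px_size_nm = image$px_size_nm, id = image$id,
               n_rows = nrow(image$heights), n_cols = ncol(image$heights),
               units = "nm")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_afm_image
#' @export
read_afm_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  h <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(h) <- NULL
  as_afm_image(h, px_size_nm = meta$px_size_nm, id = meta$id %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read per-ROI morphometry labels
#'
#' TSV schema: `roi_row`, `roi_col` (0-based), `clarity`, `dbanding`,
#' `random_orientation`, `linearity`, all 0/1.
#'
#' @param labels label data.frame (as from [generate_fibril_image()]).
#' @param path file path.
#' @export
write_morph_labels <- function(labels, path) {
  need <- c("roi_row", "roi_col", "clarity", "dbanding",
            "random_orientation", "linearity")
  stopifnot(all(need %in% names(labels)))
  utils::write.table(labels[need], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_morph_labels
#' @export
read_morph_labels <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Write / read a force curve as headered TSV
#'
#' Columns `distance_nm`, `force_nN`, `direction`; metadata (spring
#' constant, id) in `#`-prefixed header lines.
#'
#' @param curve a `force_curve`.
#' @param path file path.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# spring_constant_N_per_m: %g",
                       curve$spring_constant_N_per_m),
               sprintf("# id: %s", curve$id)), con)
  utils::write.table(
    data.frame(distance_nm = curve$distance_nm, force_nN = curve$force_nN,
               direction = curve$direction),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key, default) {
    ln <- grep(paste0("# ", key, ":"), hdr, value = TRUE, fixed = TRUE)
    if (length(ln) == 0) return(default)
    trimws(sub(paste0("# ", key, ":"), "", ln[1], fixed = TRUE))
  }
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  as_force_curve(d$distance_nm, d$force_nN,
                 direction = as.character(d$direction[1]),
                 spring_constant_N_per_m =
                   as.numeric(get_meta("spring_constant_N_per_m", "2.8")),
                 id = get_meta("id", ""))
}

#' Write / read a TCSPC decay histogram as headered TSV
#'
#' Columns `time_ns`, `counts`; bin width in a `#` header line.
#'
#' @param hist a `decay_histogram`.
#' @param path file path.
#' @export
write_decay <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin_width_ps: %g", hist$bin_width_ps),
               sprintf("# id: %s", hist$id)), con)
  utils::write.table(
    data.frame(time_ns = hist$bin_centers_ns, counts = hist$counts),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  bw <- sub("# bin_width_ps:", "",
            grep("bin_width_ps", hdr, value = TRUE)[1], fixed = TRUE)
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  as_decay_histogram(d$time_ns, d$counts, bin_width_ps = as.numeric(bw))
}

#' Write / read an FTIR spectrum as two-column CSV
#'
#' Columns `wavenumber_cm1`, `absorbance`.
#'
#' @param spectrum a `ftir_spectrum`.
#' @param path file path.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  utils::write.csv(
    data.frame(wavenumber_cm1 = spectrum$wavenumbers_cm1,
               absorbance = spectrum$absorbance),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  d <- utils::read.csv(path)
  as_ftir_spectrum(d$wavenumber_cm1, d$absorbance, id = basename(path))
}
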