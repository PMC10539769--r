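# TSV dialects used across the package. All physical quantities carry
# explicit unit suffixes in column names; no implicit units anywhere.

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("invalid TSV schema in %s: missing column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hyperfine peak table
#'
#' Schema: label, T_kelvin, shift_ppm, linewidth_hz, exchangeable (one row
#' per signal per temperature).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_peak_table <- function(path) {
  df <- .read_tsv(path, c("label", "T_kelvin", "shift_ppm",
                          "linewidth_hz", "exchangeable"))
  df$exchangeable <- as.logical(df$exchangeable)
  if (any(df$linewidth_hz <= 0, na.rm = TRUE))
    stop("invalid peak table: linewidths must be positive", call. = FALSE)
  df
}

#' Read a metal-to-proton distance table
#'
#' Schema: chain, resnum, resname, atom, fe_label, r_angstrom, bonds
#' (optional extra column ring).
#'
#' @param path TSV file.
#' @return a \code{distance_table}.
#' @export
read_distance_table <- function(path) {
  df <- .read_tsv(path, c("chain", "resnum", "resname", "atom",
                          "fe_label", "r_angstrom", "bonds"))
  if (any(df$r_angstrom <= 0))
    stop("invalid distance table: distances must be positive", call. = FALSE)
  if (any(!is.na(df$bonds) & df$bonds < 1))
    stop("invalid distance table: bond counts must be >= 1", call. = FALSE)
  if (!"ring" %in% names(df)) df$ring <- FALSE
  df$ring <- as.logical(df$ring)
  class(df) <- c("distance_table", "data.frame")
  df
}

#' @rdname read_distance_table
#' @param d a \code{distance_table}.
#' @export
write_distance_table <- function(d, path) .write_tsv(as.data.frame(d), path)

#' Read a per-residue 15N relaxation table
#'
#' Schema: resnum, R1, R2, NOE, field_mhz.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_relaxation_table <- function(path) {
  df <- .read_tsv(path, c("resnum", "R1", "R2", "NOE", "field_mhz"))
  if (any(df$R1 <= 0 | df$R2 <= 0))
    stop("invalid relaxation table: rates must be positive", call. = FALSE)
  df
}

#' Read observed NOE peak lists
#'
#' Schema: irradiated_label, peak_shift_ppm.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_noe_table <- function(path) {
  .read_tsv(path, c("irradiated_label", "peak_shift_ppm"))
}

#' Packaged example data
#'
#' Paths to the fixtures shipped with the package: the hyperfine peak table
#' and the metal-to-proton distance table of oxidized mitoNEET (transcribed
#' once; provenance noted in the file headers).
#'
#' @param file one of \code{"signals"} (peak table) or \code{"distances"}.
#' @return file path.
#' @examples
#' head(read_peak_table(clusterblind_example("signals")))
#' @export
clusterblind_example <- function(file = c("signals", "distances")) {
  file <- match.arg(file)
  fn <- switch(file, signals = "mitoneet_signals.tsv",
               distances = "mitoneet_distances.tsv")
  system.file("extdata", fn, package = "clusterblind", mustWork = TRUE)
}

#' Protons compatible with an exchangeable hyperfine signal
#'
#' Of the exchange-constrained (nitrogen-bound) protons of a candidate
#' partition, only those attached to the coordinating aromatic ring carry
#' enough delocalized spin density to produce a strongly hyperfine-shifted
#' signal; amide HN protons several sigma bonds from the metal do not.
#'
#' @param partition a \code{candidate_partition}.
#' @return character vector of proton ids.
#' @export
hyperfine_exchangeable <- function(partition) {
  tr <- partition$trace
  tr$id[tr$rule == "exchange_constrained" & tr$ring]
}
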