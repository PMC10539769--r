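#' Partition protons of cluster-bound residues into assignment classes
#'
#' Implements the distance/bond filtering used to shortlist candidates for
#' hyperfine-shifted signals:
#' \enumerate{
#'   \item protons closer than \code{r_cutoff} (default 4 Angstrom) to the
#'     nearest iron are broadened beyond detection;
#'   \item of the remainder, nitrogen-bound (exchangeable) protons can only
#'     match exchangeable signals and are set aside as exchange-constrained;
#'   \item protons more than \code{bond_max} covalent bonds from the metal
#'     (default 3) are excluded from the strongly shifted candidate set --
#'     too many intervening sigma bonds for A/h above ~1 MHz -- unless they
#'     sit on the coordinating aromatic ring, through which spin density
#'     delocalizes efficiently (\code{ring} column);
#'   \item everything else is a candidate for the strongly hyperfine-shifted
#'     signals.
#' }
#'
#' @param d a \code{distance_table} covering the cluster-bound residues,
#'   with \code{bonds} and \code{ring} columns populated.
#' @param r_cutoff beyond-detection distance, Angstrom.
#' @param bond_max maximal bond count for a non-ring proton to stay in the
#'   high-A/h class.
#' @return list of class \code{"candidate_partition"} with character-vector
#'   elements \code{beyond_detection}, \code{exchange_constrained},
#'   \code{bond_excluded}, \code{candidates} (ids
#'   \code{"<resname>-<resnum>-<atom>"}) and a \code{trace} data.frame
#'   recording which rule fired per proton.
#' @export
filter_candidates <- function(d, r_cutoff = 4.0, bond_max = 3L) {
  if (nrow(d) == 0L) stop("empty distance table", call. = FALSE)
  id <- paste(d$resname, d$resnum, d$atom, sep = "-")
  n_bound <- grepl("^H?N", d$atom) | d$atom %in% c("H", "HN") |
    grepl("^HN", d$atom)
  rule <- character(nrow(d))
  rule[d$r_angstrom < r_cutoff] <- "beyond_detection"
  todo <- rule == ""
  rule[todo & n_bound] <- "exchange_constrained"
  todo <- rule == ""
  far <- !is.na(d$bonds) & d$bonds > bond_max & !d$ring
  rule[todo & far] <- "bond_excluded"
  rule[rule == ""] <- "candidates"
  out <- split(id, factor(rule, levels = c("beyond_detection",
                                           "exchange_constrained",
                                           "bond_excluded", "candidates")))
  out <- lapply(out, as.character)
  out$trace <- data.frame(id = id, r_angstrom = d$r_angstrom,
                          bonds = d$bonds, ring = d$ring, rule = rule,
                          stringsAsFactors = FALSE)
  class(out) <- "candidate_partition"
  out
}

#' @export
print.candidate_partition <- function(x, ...) {
  cat("Candidate partition:\n")
  for (nm in c("beyond_detection", "exchange_constrained",
               "bond_excluded", "candidates"))
    cat(sprintf("  %-21s %s\n", paste0(nm, ":"),
                if (length(x[[nm]])) paste(x[[nm]], collapse = ", ")
                else "(none)"))
  invisible(x)
}

#' Predict the NOE partner pattern of a proton from the structure
#'
#' All hydrogens within \code{cutoff} of the query proton, with relative
#' NOE intensities proportional to r^-6, normalized to the strongest
#' partner. Comparing this predicted pattern with the peaks observed in a
#' 1D NOE difference experiment discriminates between assignment candidates.
#'
#' @param s a protonated \code{pdb_structure}.
#' @param proton_id \code{"<resname>-<resnum>-<atom>"} (chain-ambiguous ids
#'   take the first match) or \code{"<chain>-<resname>-<resnum>-<atom>"}.
#' @param cutoff Angstrom (default 5).
#' @return data.frame: partner_id, r_angstrom, intensity (max 1), sorted by
#'   decreasing intensity.
#' @export
predict_noe_partners <- function(s, proton_id, cutoff = 5.0) {
  stopifnot(inherits(s, "pdb_structure"))
  parts <- strsplit(proton_id, "-", fixed = TRUE)[[1]]
  if (length(parts) == 4L) {
    sel <- s$chain == parts[1] & s$resname == parts[2] &
      s$resnum == as.integer(parts[3]) & s$atom == parts[4]
  } else if (length(parts) == 3L) {
    sel <- s$resname == parts[1] & s$resnum == as.integer(parts[2]) &
      s$atom == parts[3]
  } else stop("proton_id must be resname-resnum-atom", call. = FALSE)
  idx <- which(sel & s$element == "H")
  if (!length(idx)) stop(sprintf("proton '%s' not found", proton_id),
                         call. = FALSE)
  idx <- idx[1]
  p0 <- c(s$x[idx], s$y[idx], s$z[idx])
  hyd <- which(s$element == "H")
  hyd <- setdiff(hyd, idx)
  r <- sqrt((s$x[hyd] - p0[1])^2 + (s$y[hyd] - p0[2])^2 +
              (s$z[hyd] - p0[3])^2)
  keep <- r < cutoff
  hyd <- hyd[keep]; r <- r[keep]
  if (!length(hyd))
    return(data.frame(partner_id = character(), r_angstrom = numeric(),
                      intensity = numeric(), stringsAsFactors = FALSE))
  inten <- r^-6 / max(r^-6)
  o <- order(-inten)
  data.frame(
    partner_id = paste(s$resname[hyd], s$resnum[hyd], s$atom[hyd],
                       sep = "-")[o],
    r_angstrom = r[o], intensity = inten[o], stringsAsFactors = FALSE)
}

# all injective mappings of signals (rows) onto candidates: list of integer
# vectors idx[i] = candidate index for signal i
.injections <- function(n_sig, n_cand) {
  if (n_sig == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == n_sig) { out[[length(out) + 1L]] <<- prefix; return() }
    for (k in remaining) rec(c(prefix, k), setdiff(remaining, k))
  }
  rec(integer(0), seq_len(n_cand))
  out
}

#' Match hyperfine signals to candidate protons by NOE patterns
#'
#' Exhaustive one-to-one matching of irradiated signals to candidate
#' protons, scoring each mapping by the number of observed NOE peaks that
#' fall within \code{tol_ppm} of a predicted partner shift, weighted by the
#' predicted relative intensity. Mappings are enumerated exhaustively
#' (candidate sets are small); ties at the top score are reported as
#' ambiguous, never broken silently.
#'
#' @param candidates character vector of candidate proton ids.
#' @param signals character vector of signal labels that were irradiated.
#' @param observed named list (per signal label) of numeric vectors of
#'   observed NOE peak shifts, ppm.
#' @param predicted named list (per candidate id) of data.frames with
#'   columns \code{shift_ppm} and \code{intensity}: the predicted partner
#'   shifts (from \code{\link{predict_noe_partners}} joined to a shift
#'   table).
#' @param tol_ppm matching tolerance, ppm (default 0.05).
#' @return object of class \code{"assignment_result"}: \code{assignment}
#'   (named character; NA for unassigned), \code{score}, \code{ambiguous}
#'   (logical), \code{alternatives} (list of equally scoring mappings),
#'   per-signal score trace.
#' @export
match_assignments <- function(candidates, signals, observed, predicted,
                              tol_ppm = 0.05) {
  n_sig <- length(signals); n_cand <- length(candidates)
  pair_score <- matrix(0, n_sig, n_cand,
                       dimnames = list(signals, candidates))
  for (i in seq_len(n_sig)) {
    obs <- observed[[signals[i]]]
    if (is.null(obs)) next
    for (j in seq_len(n_cand)) {
      pred <- predicted[[candidates[j]]]
      if (is.null(pred) || nrow(pred) == 0L) next
      for (o in obs) {
        hit <- which(abs(pred$shift_ppm - o) <= tol_ppm)
        if (length(hit))
          pair_score[i, j] <- pair_score[i, j] + max(pred$intensity[hit])
      }
    }
  }
  if (n_sig > n_cand) {
    # more signals than candidates: assign candidates to signals instead,
    # leaving the surplus signals unassigned
    cmaps <- .injections(n_cand, n_sig)
    maps <- lapply(cmaps, function(cm) {
      m <- rep(NA_integer_, n_sig)
      m[cm] <- seq_len(n_cand)
      m
    })
  } else {
    maps <- .injections(n_sig, n_cand)
  }
  scores <- vapply(maps, function(m) {
    ok <- !is.na(m)
    sum(pair_score[cbind(which(ok), m[ok])])
  }, numeric(1))
  best <- max(scores)
  top <- which(abs(scores - best) < 1e-12)
  assignment <- stats::setNames(candidates[maps[[top[1]]]], signals)
  # a signal is individually ambiguous if the top mappings disagree on it
  amb_per_sig <- vapply(seq_len(n_sig), function(i)
    length(unique(vapply(top, function(k) maps[[k]][i], integer(1)))) > 1L,
    logical(1))
  assignment[amb_per_sig] <- NA_character_
  structure(list(
    assignment = assignment, score = best,
    ambiguous = length(top) > 1L,
    alternatives = lapply(top, function(k)
      stats::setNames(candidates[maps[[k]]], signals)),
    pair_scores = pair_score), class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("NOE-pattern assignment", if (x$ambiguous) "(AMBIGUOUS)" else "",
      "\n")
  for (sg in names(x$assignment))
    cat(sprintf("  %s -> %s\n", sg,
                if (is.na(x$assignment[[sg]])) "ambiguous/unassigned"
                else x$assignment[[sg]]))
  cat(sprintf("  total score %.3g over %d equally good mapping(s)\n",
              x$score, length(x$alternatives)))
  invisible(x)
}

#' Combined amide chemical-shift perturbation
#'
#' \deqn{\Delta_{HN} = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N/5)^2}}
#' The nitrogen shift difference is scaled by 1/5 to account for the wider
#' 15N shift range before combining with the proton difference.
#'
#' @param d_H,d_N proton and nitrogen shift differences, ppm.
#' @return combined perturbation, ppm (>= 0).
#' @examples
#' delta_HN(0.1, 0.5)  # 0.1414
#' delta_HN(0, 1.0)    # 0.2
#' @export
delta_HN <- function(d_H, d_N) {
  if (any(!is.finite(d_H)) || any(!is.finite(d_N)))
    stop("shift differences must be finite", call. = FALSE)
  sqrt(d_H^2 + (d_N / 5)^2)
}

#' Significance threshold for shift perturbations
#'
#' Residues whose combined perturbation exceeds the mean plus one standard
#' deviation over all residues are flagged significant.
#'
#' @param records data.frame with columns \code{residue}, \code{d_H},
#'   \code{d_N} (ppm).
#' @return the input with \code{delta_HN} and \code{significant} columns
#'   appended; the threshold is attached as attribute
#'   \code{"threshold_ppm"}.
#' @export
perturbation_significance <- function(records) {
  stopifnot(all(c("residue", "d_H", "d_N") %in% names(records)))
  records$delta_HN <- delta_HN(records$d_H, records$d_N)
  thr <- mean(records$delta_HN) + stats::sd(records$delta_HN)
  records$significant <- records$delta_HN > thr
  attr(records, "threshold_ppm") <- thr
  records
}
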