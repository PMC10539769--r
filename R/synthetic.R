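#' Specification of a toy [Fe2S2] site
#'
#' A minimal, fully determined cluster model: two irons bridged by two
#' sulfides, Cys-like thiolate ligands (S at 2.3 Angstrom from an iron) and
#' one His-like imidazole nitrogen ligand (N at 2.1 Angstrom), plus probe
#' protons placed at chosen nearest-iron distances. Every pipeline stage can
#' be exercised against this known ground truth without any external
#' structure.
#'
#' @param fe_fe Fe-Fe distance, Angstrom (default 2.7).
#' @param proton_r nearest-iron distances at which probe protons are placed,
#'   Angstrom (may be empty).
#' @param n_cys number of Cys-like S ligands (default 3).
#' @param n_his number of His-like N ligands (default 1).
#' @param partner_offset distance (Angstrom) at which a geminal-like
#'   companion proton is placed radially outward from each probe proton
#'   (default 1.75, the methylene H-H separation), giving every probe a
#'   predictable strongest NOE partner; NA places no companions.
#' @param seed integer seed fixing all randomness in the placement.
#' @return object of class \code{"toy_site_spec"}.
#' @export
toy_site_spec <- function(fe_fe = 2.7,
                          proton_r = c(2.98, 3.5, 4.35, 4.94, 5.18),
                          n_cys = 3, n_his = 1, partner_offset = 1.75,
                          seed = 1) {
  if (fe_fe <= 0 || any(proton_r <= 0))
    stop("distances must be positive", call. = FALSE)
  structure(list(fe_fe = fe_fe, proton_r = proton_r,
                 n_cys = n_cys, n_his = n_his,
                 partner_offset = partner_offset, seed = seed),
            class = "toy_site_spec")
}

# deterministic unit vectors roughly tetrahedral around each iron
.ligand_dirs <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
}

#' Build a toy [Fe2S2] structure with ground-truth distances
#'
#' Places Fe1 at the origin and Fe2 on the x axis, bridging sulfides in the
#' xz plane, ligand atoms on outward tetrahedral directions and probe
#' protons at the requested nearest-iron distances (alternating between the
#' two irons, on randomized outward directions, re-drawn until no atom pair
#' is closer than 0.8 Angstrom and the nearest iron really is the intended
#' one). The returned structure is PDB-writable and round-trips through
#' \code{\link{write_pdb}} / \code{\link{read_pdb}}.
#'
#' @param spec a \code{\link{toy_site_spec}}.
#' @return list with \code{structure} (a \code{pdb_structure}) and
#'   \code{truth} (a \code{distance_table} of the probe protons: resname
#'   PRB, atom Hk).
#' @export
make_toy_structure <- function(spec = toy_site_spec()) {
  stopifnot(inherits(spec, "toy_site_spec"))
  set.seed(spec$seed)
  fe1 <- c(0, 0, 0); fe2 <- c(spec$fe_fe, 0, 0)
  mid <- spec$fe_fe / 2
  # bridging sulfides: Fe-S(bridge) ~ 2.2 A
  hz <- sqrt(max(2.2^2 - mid^2, 0.25))
  atoms <- list(
    list("HETATM", "FE1", "FES", "A", 901L, fe1, "FE"),
    list("HETATM", "FE2", "FES", "A", 901L, fe2, "FE"),
    list("HETATM", "S1", "FES", "A", 901L, c(mid, 0, hz), "S"),
    list("HETATM", "S2", "FES", "A", 901L, c(mid, 0, -hz), "S"))
  dirs <- .ligand_dirs()
  # terminal ligands: Cys S at 2.3 A, His N at 2.1 A, outward directions
  li <- 0L
  for (k in seq_len(spec$n_cys)) {
    li <- li + 1L
    fe <- if (k %% 2 == 1) fe1 else fe2
    sgn <- if (k %% 2 == 1) -1 else 1
    dir <- dirs[(k - 1L) %% 4 + 1L, ] * c(sgn, 1, 1)
    atoms[[length(atoms) + 1L]] <-
      list("ATOM", "SG", "CYS", "A", 10L + li, fe + 2.3 * dir, "S")
  }
  for (k in seq_len(spec$n_his)) {
    li <- li + 1L
    fe <- if ((spec$n_cys + k) %% 2 == 1) fe1 else fe2
    sgn <- if ((spec$n_cys + k) %% 2 == 1) -1 else 1
    dir <- dirs[(spec$n_cys + k - 1L) %% 4 + 1L, ] * c(sgn, 1, 1)
    atoms[[length(atoms) + 1L]] <-
      list("ATOM", "ND1", "HIS", "A", 10L + li, fe + 2.1 * dir, "N")
  }
  existing <- do.call(rbind, lapply(atoms, function(a) a[[6]]))
  # probe protons at requested nearest-iron distances
  truth <- NULL
  for (k in seq_along(spec$proton_r)) {
    r <- spec$proton_r[k]
    fe_near <- if (k %% 2 == 1) fe1 else fe2
    fe_far <- if (k %% 2 == 1) fe2 else fe1
    ok <- FALSE
    for (try in 1:200) {
      v <- stats::rnorm(3)
      sgn <- if (k %% 2 == 1) -1 else 1
      v[1] <- sgn * abs(v[1])           # point away from the other iron
      v <- v / sqrt(sum(v^2))
      p <- fe_near + r * v
      d_far <- sqrt(sum((p - fe_far)^2))
      dmin <- min(sqrt(rowSums(sweep(existing, 2, p)^2)))
      if (d_far > r + 1e-6 && dmin >= 0.8) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible geometry: could not place probe proton",
                  call. = FALSE)
    atoms[[length(atoms) + 1L]] <-
      list("ATOM", paste0("H", k), "PRB", "A", 100L + k, p, "H")
    existing <- rbind(existing, p)
    if (is.finite(spec$partner_offset) && spec$partner_offset > 0) {
      q <- p + spec$partner_offset * v   # radially outward companion
      atoms[[length(atoms) + 1L]] <-
        list("ATOM", paste0("G", k), "PRB", "A", 100L + k, q, "H")
      existing <- rbind(existing, q)
    }
    truth <- rbind(truth, data.frame(
      chain = "A", resnum = 100L + k, resname = "PRB",
      atom = paste0("H", k),
      fe_label = if (k %% 2 == 1) "FE1" else "FE2",
      r_angstrom = r, bonds = NA_integer_, ring = FALSE,
      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    data.frame(record = a[[1]], serial = i, atom = a[[2]], altloc = " ",
               resname = a[[3]], chain = a[[4]], resnum = a[[5]],
               x = a[[6]][1], y = a[[6]][2], z = a[[6]][3],
               occupancy = 1, element = a[[7]], is_water = FALSE,
               stringsAsFactors = FALSE)
  }))
  class(df) <- c("pdb_structure", "data.frame")
  if (!is.null(truth)) class(truth) <- c("distance_table", "data.frame")
  list(structure = df, truth = truth)
}

#' Forward-model a hyperfine peak table
#'
#' Generates a signals table in the packaged peak-table schema (label,
#' T_kelvin, shift_ppm, linewidth_hz, exchangeable) from the coupled-dimer
#' contact-shift model plus a diamagnetic offset, with linewidths from the
#' r^-6 calibration and optional Gaussian noise on the shifts.
#'
#' @param sys a \code{\link{spin_system}}.
#' @param couplings data.frame with columns \code{label}, \code{A_MHz},
#'   \code{site}, \code{r_angstrom}, \code{exchangeable}.
#' @param temperatures Kelvin (default c(283, 293)).
#' @param calibration list(r_ref=, dnu_ref=) for the linewidths.
#' @param dia_offset_ppm diamagnetic offset added to every shift.
#' @param noise_ppm Gaussian noise sd on shifts (0 = noiseless).
#' @param seed integer seed.
#' @return data.frame: label, T_kelvin, shift_ppm, linewidth_hz,
#'   exchangeable.
#' @export
make_peak_table <- function(sys, couplings,
                            temperatures = c(283, 293),
                            calibration = list(r_ref = 4.94, dnu_ref = 2500),
                            dia_offset_ppm = 4.0, noise_ppm = 0, seed = 1) {
  stopifnot(inherits(sys, "spin_system"))
  if (length(temperatures) < 1L) stop("need at least one temperature",
                                      call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(couplings))) {
    cp <- couplings[i, ]
    dnu <- calibrated_prediction(calibration$r_ref, calibration$dnu_ref,
                                 cp$r_angstrom)
    for (Tk in temperatures) {
      sh <- contact_shift(sys, cp$A_MHz, Tk, site = cp$site) +
        dia_offset_ppm + stats::rnorm(1, 0, noise_ppm)
      rows[[length(rows) + 1L]] <- data.frame(
        label = cp$label, T_kelvin = Tk, shift_ppm = sh,
        linewidth_hz = dnu, exchangeable = cp$exchangeable,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a rigid-rotor 15N relaxation table
#'
#' Per-residue R1, R2 and heteronuclear NOE for an isotropically tumbling
#' rigid molecule with multiplicative Gaussian noise, in the relaxation TSV
#' schema (resnum, R1, R2, NOE, field_mhz).
#'
#' @param tau_c_ns rotational correlation time, ns (1-50).
#' @param field_mhz proton frequency, MHz.
#' @param n_residues number of residues.
#' @param noise_frac fractional (multiplicative) noise sd on R1 and R2.
#' @param seed integer seed.
#' @return data.frame: resnum, R1, R2, NOE, field_mhz.
#' @export
make_relaxation_table <- function(tau_c_ns, field_mhz = 500,
                                  n_residues = 40, noise_frac = 0.05,
                                  seed = 1) {
  if (tau_c_ns < 1 || tau_c_ns > 50)
    stop("tau_c must be in 1-50 ns", call. = FALSE)
  set.seed(seed)
  ideal <- simulate_15N_relaxation(tau_c_ns * 1e-9, field_mhz)
  data.frame(
    resnum = seq_len(n_residues),
    R1 = ideal$R1 * (1 + stats::rnorm(n_residues, 0, noise_frac)),
    R2 = ideal$R2 * (1 + stats::rnorm(n_residues, 0, noise_frac)),
    NOE = rep(ideal$NOE, n_residues),
    field_mhz = field_mhz)
}

#' Simulate observed NOE difference-spectrum peak lists
#'
#' For a known ground-truth assignment of irradiated signals to protons of
#' a structure, emits the peak shifts their predicted NOE partners would
#' produce, with random dropout emulating the very sparse, weak NOEs
#' measurable from fast-relaxing hyperfine signals.
#'
#' @param s a protonated \code{pdb_structure}.
#' @param truth named character vector: signal label -> proton id.
#' @param shift_table named numeric vector: proton id -> 1H shift, ppm
#'   (partners without a shift are dropped).
#' @param dropout fraction of partner peaks removed at random (0-1).
#' @param cutoff NOE distance cutoff, Angstrom.
#' @param seed integer seed.
#' @return data.frame: irradiated_label, peak_shift_ppm.
#' @export
make_noe_observations <- function(s, truth, shift_table, dropout = 0,
                                  cutoff = 5.0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (lb in names(truth)) {
    partners <- predict_noe_partners(s, truth[[lb]], cutoff)
    sh <- shift_table[partners$partner_id]
    sh <- sh[!is.na(sh)]
    if (dropout > 0 && length(sh))
      sh <- sh[stats::runif(length(sh)) >= dropout]
    for (p in sh)
      rows[[length(rows) + 1L]] <- data.frame(
        irradiated_label = lb, peak_shift_ppm = as.numeric(p),
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(irradiated_label = character(),
                      peak_shift_ppm = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
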