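#' Read a protein structure from PDB text
#'
#' Parses ATOM/HETATM records (fixed-width PDB v3 columns) into an atom
#' table. Alternate locations are resolved by keeping, per (chain, residue,
#' atom), the altloc with the highest occupancy; waters (HOH/WAT) are kept
#' and flagged. No installed R package reads PDB, so the fixed-width format
#' is parsed directly here.
#'
#' @param pdb either a file path or a character vector of PDB lines.
#' @return object of class \code{"pdb_structure"}: a data.frame with columns
#'   \code{record}, \code{serial}, \code{atom}, \code{altloc},
#'   \code{resname}, \code{chain}, \code{resnum}, \code{x}, \code{y},
#'   \code{z}, \code{occupancy}, \code{element}, \code{is_water}.
#' @examples
#' s <- read_pdb(c(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C"))
#' nrow(s)
#' @export
read_pdb <- function(pdb) {
  lines <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb))
    readLines(pdb, warn = FALSE)
  else unlist(strsplit(pdb, "\n", fixed = TRUE))
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  if (!any(keep))
    stop("PDB parse error: no ATOM/HETATM records found", call. = FALSE)
  lines <- lines[keep]
  fw <- function(a, b) trimws(substr(lines, a, b))
  num <- function(a, b) suppressWarnings(as.numeric(fw(a, b)))
  x <- num(31, 38); y <- num(39, 46); z <- num(47, 54)
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    stop(sprintf("PDB parse error: malformed coordinates in line: %s",
                 lines[bad[1]]), call. = FALSE)
  occ <- num(55, 60); occ[!is.finite(occ)] <- 1
  element <- fw(77, 78)
  atom_name <- fw(13, 16)
  # infer element from the atom name when column 77-78 is absent
  noel <- element == ""
  if (any(noel)) {
    guess <- sub("^[0-9]*", "", atom_name[noel])
    element[noel] <- ifelse(grepl("^FE", guess), "FE",
                            substr(guess, 1, 1))
  }
  df <- data.frame(
    record = trimws(substr(lines, 1, 6)),
    serial = suppressWarnings(as.integer(fw(7, 11))),
    atom = atom_name,
    altloc = substr(lines, 17, 17),
    resname = fw(18, 20),
    chain = substr(lines, 22, 22),
    resnum = suppressWarnings(as.integer(fw(23, 26))),
    x = x, y = y, z = z,
    occupancy = occ,
    element = toupper(element),
    stringsAsFactors = FALSE)
  df$is_water <- df$resname %in% c("HOH", "WAT", "DOD")
  # altloc resolution: keep highest occupancy per (chain, resnum, resname, atom)
  if (any(df$altloc != " ")) {
    key <- paste(df$chain, df$resnum, df$resname, df$atom, sep = "|")
    ord <- order(key, -df$occupancy)
    df <- df[ord, ][!duplicated(key[ord]), ]
    df <- df[order(df$serial), ]
  }
  rownames(df) <- NULL
  class(df) <- c("pdb_structure", "data.frame")
  df
}

#' Write a structure as PDB text
#'
#' @param s a \code{pdb_structure}.
#' @param file optional path; when NULL the lines are returned invisibly.
#' @return character vector of PDB lines (invisibly when written to file).
#' @export
write_pdb <- function(s, file = NULL) {
  stopifnot(inherits(s, "pdb_structure"))
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    s$record, seq_len(nrow(s)),
    ifelse(nchar(s$atom) >= 4, s$atom, paste0(" ", s$atom)),
    " ", s$resname, s$chain, s$resnum, s$x, s$y, s$z, s$occupancy, 0,
    s$element)
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("PDB structure: %d atoms, %d chains, %d residues",
              nrow(x), length(unique(x$chain)),
              length(unique(paste(x$chain, x$resnum)))))
  nmet <- sum(x$element %in% c("FE", "ZN", "CU", "MN", "NI", "CO"))
  if (nmet) cat(sprintf(", %d metal atoms", nmet))
  cat("\n")
  invisible(x)
}

.xyz <- function(s) as.matrix(s[, c("x", "y", "z")])

#' Locate metal sites and group them into clusters
#'
#' One site per matching metal atom; metals closer than
#' \code{cluster_cutoff} (default 3.5 Angstrom, spanning the ~2.7 Angstrom
#' Fe-Fe separation of an [Fe2S2] cluster) share a cluster id.
#'
#' @param s a \code{pdb_structure}.
#' @param elements element symbols regarded as metals (default \code{"FE"}).
#' @param cluster_cutoff metal-metal distance grouping cutoff, Angstrom.
#' @return data.frame of class \code{"metal_sites"}: label, cluster,
#'   chain, resnum, x, y, z, element.
#' @export
find_metal_sites <- function(s, elements = "FE", cluster_cutoff = 3.5) {
  stopifnot(inherits(s, "pdb_structure"))
  m <- s[s$element %in% toupper(elements), ]
  if (nrow(m) == 0L)
    stop(sprintf("no metal site: no atom with element in {%s}",
                 paste(elements, collapse = ",")), call. = FALSE)
  xyz <- .xyz(m)
  # single-linkage grouping by the cutoff
  n <- nrow(m)
  cluster <- seq_len(n)
  if (n > 1L) {
    dm <- as.matrix(stats::dist(xyz))
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (dm[i, j] < cluster_cutoff && cluster[j] != cluster[i]) {
          cluster[cluster == cluster[j]] <- cluster[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  cluster <- match(cluster, unique(cluster))
  out <- data.frame(
    label = paste0(m$element, seq_len(n)),
    cluster = cluster,
    chain = m$chain, resnum = m$resnum,
    x = m$x, y = m$y, z = m$z, element = m$element,
    stringsAsFactors = FALSE)
  class(out) <- c("metal_sites", "data.frame")
  out
}

# Covalent connectivity by distance thresholds: 1.9 A generic, 2.6 A when
# one partner is a metal (Fe-S / Fe-N coordination bonds). H atoms bond at
# <= 1.2 A to their heavy atom; the generic threshold covers that.
.covalent_edges <- function(s, generic = 1.9, metal = 2.6) {
  xyz <- .xyz(s)
  n <- nrow(s)
  is_metal <- s$element %in% c("FE", "ZN", "CU", "MN", "NI", "CO")
  dm <- as.matrix(stats::dist(xyz))
  thr <- matrix(generic, n, n)
  thr[is_metal, ] <- metal; thr[, is_metal] <- metal
  adj <- dm > 0.01 & dm < thr
  diag(adj) <- FALSE
  adj
}

# BFS shortest path length over the covalent graph from atom index `from`
.bond_count <- function(adj, from, to) {
  n <- nrow(adj)
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  frontier <- from
  while (length(frontier) && is.na(dist[to])) {
    nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(dist))
    if (!length(nxt)) break
    dist[nxt] <- dist[frontier[1]] + 1L
    frontier <- nxt
  }
  dist[to]
}

#' Metal-to-proton distance table
#'
#' For every selected hydrogen, the distance to the nearest metal site (and
#' to each site). When the proton's residue coordinates a metal (some atom
#' of the residue within the coordination threshold), the number of covalent
#' bonds from the metal to the proton is computed over a distance-threshold
#' covalent graph; otherwise the bond count is NA.
#'
#' @param s a protonated \code{pdb_structure}.
#' @param sites metal sites from \code{\link{find_metal_sites}} (computed
#'   when NULL).
#' @param selection \code{"all"} for every hydrogen, \code{"HN"} for
#'   backbone amides (atom name H or HN), or a character vector of atom
#'   names.
#' @param compute_bonds logical; BFS bond counts for coordinating residues.
#' @return data.frame of class \code{"distance_table"}: chain, resnum,
#'   resname, atom, fe_label, r_angstrom, bonds, ring. \code{fe_label} is
#'   the nearest metal; \code{ring} flags protons attached to an aromatic
#'   ring atom of a coordinating residue (relevant to hyperfine-class
#'   filtering).
#' @export
metal_proton_distances <- function(s, sites = NULL, selection = "all",
                                   compute_bonds = TRUE) {
  stopifnot(inherits(s, "pdb_structure"))
  if (is.null(sites)) sites <- find_metal_sites(s)
  hyd <- s$element == "H"
  if (identical(selection, "HN")) {
    sel <- hyd & s$atom %in% c("H", "HN")
  } else if (identical(selection, "all")) {
    sel <- hyd
  } else {
    sel <- hyd & s$atom %in% selection
  }
  if (!any(sel)) {
    warning("selection matches no hydrogens; empty distance table")
    out <- data.frame(chain = character(), resnum = integer(),
                      resname = character(), atom = character(),
                      fe_label = character(), r_angstrom = numeric(),
                      bonds = integer(), ring = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("distance_table", "data.frame")
    return(out)
  }
  hxyz <- .xyz(s[sel, ])
  mxyz <- as.matrix(sites[, c("x", "y", "z")])
  dmat <- sqrt(outer(rowSums(hxyz^2), rep(1, nrow(mxyz))) +
                 outer(rep(1, nrow(hxyz)), rowSums(mxyz^2)) -
                 2 * hxyz %*% t(mxyz))
  nearest <- apply(dmat, 1, which.min)
  rmin <- dmat[cbind(seq_len(nrow(dmat)), nearest)]
  if (any(rmin < 1e-6))
    warning("degenerate geometry: proton coincident with a metal site")

  hsub <- s[sel, ]
  bonds <- rep(NA_integer_, nrow(hsub))
  ring <- rep(FALSE, nrow(hsub))
  if (compute_bonds) {
    adj <- .covalent_edges(s)
    ring_atoms <- c("CG", "ND1", "CD2", "CE1", "NE2",   # His imidazole
                    "CD1", "CE2", "CZ", "CZ2", "CZ3", "CE3", "CH2",
                    "NE1", "CD")
    aromatic_res <- c("HIS", "PHE", "TYR", "TRP")
    sel_idx <- which(sel)
    metal_idx <- vapply(seq_len(nrow(sites)), function(k) {
      hits <- which(abs(s$x - sites$x[k]) < 1e-4 &
                      abs(s$y - sites$y[k]) < 1e-4 &
                      abs(s$z - sites$z[k]) < 1e-4)
      hits[1]
    }, integer(1))
    for (i in seq_len(nrow(hsub))) {
      mi <- metal_idx[nearest[i]]
      hi <- sel_idx[i]
      # does the proton's residue coordinate this metal?
      res_atoms <- which(s$chain == hsub$chain[i] &
                           s$resnum == hsub$resnum[i] &
                           s$resname == hsub$resname[i])
      coordinates <- any(adj[mi, res_atoms])
      if (coordinates) bonds[i] <- .bond_count(adj, mi, hi)
      # ring flag: attachment heavy atom is an aromatic ring atom
      att <- res_atoms[adj[hi, res_atoms] & s$element[res_atoms] != "H"]
      if (length(att) && hsub$resname[i] %in% aromatic_res &&
          s$atom[att[1]] %in% ring_atoms)
        ring[i] <- TRUE
    }
  }
  out <- data.frame(chain = hsub$chain, resnum = hsub$resnum,
                    resname = hsub$resname, atom = hsub$atom,
                    fe_label = sites$label[nearest],
                    r_angstrom = rmin, bonds = bonds, ring = ring,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("distance_table", "data.frame")
  out
}

#' Build backbone amide protons with idealized geometry
#'
#' Adds an H atom on each backbone nitrogen at 1.01 Angstrom along the
#' direction opposing the bisector of the N-CA and N-C(i-1) bonds, i.e. in
#' the C(i-1)-N-CA plane with equal H-N-CA and H-N-C angles. Prolines,
#' chain N-termini and residues whose upstream carbonyl carbon is missing
#' are skipped (with a warning for the latter); residues that already carry
#' an amide proton are left untouched. Side-chain protonation is out of
#' scope and accepted on input from external tools.
#'
#' @param s a \code{pdb_structure}.
#' @return the structure with amide H atoms appended.
#' @export
build_amide_protons <- function(s) {
  stopifnot(inherits(s, "pdb_structure"))
  prot <- s[s$record == "ATOM" & !s$is_water, ]
  added <- list()
  skipped <- 0L
  for (ch in unique(prot$chain)) {
    resnums <- sort(unique(prot$resnum[prot$chain == ch]))
    for (rn in resnums) {
      res <- prot[prot$chain == ch & prot$resnum == rn, ]
      if (res$resname[1] == "PRO") next
      if (any(res$atom %in% c("H", "HN"))) next
      if (!(rn - 1L) %in% resnums) next  # chain N-terminus
      getxyz <- function(df, nm) {
        row <- df[df$atom == nm, , drop = FALSE]
        if (nrow(row) == 0L) return(NULL)
        c(row$x[1], row$y[1], row$z[1])
      }
      N <- getxyz(res, "N"); CA <- getxyz(res, "CA")
      prev <- prot[prot$chain == ch & prot$resnum == rn - 1L, ]
      Cp <- getxyz(prev, "C")
      if (is.null(N) || is.null(CA)) next
      if (is.null(Cp)) {
        warning(sprintf("residue %s%d: upstream C missing, amide H skipped",
                        ch, rn))
        skipped <- skipped + 1L
        next
      }
      u1 <- (CA - N) / sqrt(sum((CA - N)^2))
      u2 <- (Cp - N) / sqrt(sum((Cp - N)^2))
      b <- -(u1 + u2)
      b <- b / sqrt(sum(b^2))
      H <- N + 1.01 * b
      added[[length(added) + 1L]] <- data.frame(
        record = "ATOM", serial = NA_integer_, atom = "H", altloc = " ",
        resname = res$resname[1], chain = ch, resnum = rn,
        x = H[1], y = H[2], z = H[3], occupancy = 1, element = "H",
        is_water = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(added)) {
    s <- rbind(as.data.frame(s), do.call(rbind, added))
    s$serial <- seq_len(nrow(s))
    class(s) <- c("pdb_structure", "data.frame")
  }
  s
}

#' Count protons within a radius of the nearest metal
#'
#' Strict inequality: protons at exactly the radius are not counted.
#'
#' @param d a \code{distance_table}.
#' @param radius Angstrom, > 0.
#' @param selection optional atom-name filter (e.g. \code{c("H","HN")});
#'   NULL counts every row.
#' @param chains optional chain filter (e.g. one subunit of a dimer).
#' @return integer count.
#' @export
count_protons_within <- function(d, radius, selection = NULL, chains = NULL) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  keep <- rep(TRUE, nrow(d))
  if (!is.null(selection)) keep <- keep & d$atom %in% selection
  if (!is.null(chains)) keep <- keep & d$chain %in% chains
  sum(keep & d$r_angstrom < radius)
}

#' Blind-sphere radius from undetected amides
#'
#' The blind sphere of an experiment is the region around the paramagnetic
#' centre whose signals are broadened beyond detection. Its radius is
#' estimated as the largest nearest-metal distance among the undetected
#' amides, after setting aside those farther than \code{outlier_cutoff}
#' (undetected for non-paramagnetic reasons: exchange, disorder, overlap);
#' the result is rounded to 0.5 Angstrom, matching the granularity at which
#' such radii are quoted.
#'
#' @param d a \code{distance_table} of amide protons.
#' @param undetected character vector of undetected amide ids, format
#'   \code{"<chain>:<resnum>"} or \code{"<chain>:<resnum>:<atom>"}.
#' @param outlier_cutoff Angstrom; undetected amides beyond it are reported
#'   separately, not used for the radius.
#' @return list of class \code{"blind_sphere"}: \code{radius} (Angstrom,
#'   rounded to 0.5), \code{n_inside}, \code{outliers} (ids beyond cutoff).
#' @examples
#' d <- data.frame(chain = "A", resnum = 1:4, resname = "ALA", atom = "H",
#'                 fe_label = "FE1", r_angstrom = c(3, 5.5, 7.9, 14),
#'                 bonds = NA, ring = FALSE)
#' class(d) <- c("distance_table", "data.frame")
#' blind_sphere_radius(d, paste0("A:", 1:4))  # 8.0, one outlier
#' @export
blind_sphere_radius <- function(d, undetected, outlier_cutoff = 12) {
  ids2 <- paste(d$chain, d$resnum, sep = ":")
  ids3 <- paste(d$chain, d$resnum, d$atom, sep = ":")
  hit <- ids2 %in% undetected | ids3 %in% undetected
  if (length(undetected) &&
      !all(undetected %in% c(ids2, ids3)))
    stop("undetected ids not all present in the distance table",
         call. = FALSE)
  r <- d$r_angstrom[hit]
  out_ids <- ids3[hit][r >= outlier_cutoff]
  r_in <- r[r < outlier_cutoff]
  radius <- if (length(r_in)) round(max(r_in) * 2) / 2 else 0
  structure(list(radius = radius, n_inside = length(r_in),
                 outliers = out_ids,
                 no_paramagnetic_blind_sphere = length(r_in) == 0L),
            class = "blind_sphere")
}

#' @export
print.blind_sphere <- function(x, ...) {
  if (x$no_paramagnetic_blind_sphere) {
    cat("No paramagnetic blind sphere (all undetected amides beyond",
        "the outlier cutoff)\n")
  } else {
    cat(sprintf("Blind-sphere radius: %.1f Angstrom (%d undetected amides",
                x$radius, x$n_inside))
    cat(sprintf(", %d outliers attributed to non-paramagnetic causes)\n",
                length(x$outliers)))
  }
  invisible(x)
}
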