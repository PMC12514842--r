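#' Default van der Waals radii (Angstrom)
#'
#' A single pinned radii set keyed by element so outputs are comparable
#' across runs; users may override per element or per atom name.
#' @export
default_vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                       F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90, I = 1.98)

#' Parameters for solvent-accessible surface area
#'
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, a
#'   water-sized probe)
#' @param n_points number of deterministic sphere sample points per atom
#'   (default 960; sampling error scales like area/sqrt(n_points))
#' @param radii named vector of van der Waals radii by element
#' @param radii_override named vector of radii by atom name, consulted
#'   before the element table (used e.g. for pseudo-atom sphere systems)
#' @return list of class `SasaParams`
#' @export
sasa_params <- function(probe_radius = 1.4, n_points = 960L,
                        radii = default_vdw_radii,
                        radii_override = NULL) {
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (n_points < 60L) stop("n_points must be at least 60")
  structure(list(probe_radius = probe_radius, n_points = as.integer(n_points),
                 radii = radii, radii_override = radii_override),
            class = "SasaParams")
}

#' Deterministic golden-spiral lattice on the unit sphere
#' @param n number of points
#' @return n x 3 matrix of unit vectors
#' @export
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

.atom_radii <- function(atoms, params) {
  r <- rep(NA_real_, nrow(atoms))
  if (!is.null(params$radii_override)) {
    hit <- match(atoms$atom, names(params$radii_override))
    r[!is.na(hit)] <- params$radii_override[hit[!is.na(hit)]]
  }
  need <- is.na(r)
  if (any(need)) {
    hit <- match(atoms$element[need], names(params$radii))
    r[need] <- params$radii[hit]
  }
  if (anyNA(r)) {
    bad <- atoms[is.na(r), , drop = FALSE][1L, ]
    stop(sprintf("no van der Waals radius for atom %s/%d/%s (element '%s')",
                 bad$chain, bad$resseq, bad$atom, bad$element))
  }
  unname(r)
}

# Local orthonormal frame per atom derived from its nearest occluding
# neighbors. Because the frame is built only from vectors to atoms that can
# occlude the sphere, (a) a rigid motion of the whole model rotates the
# sample lattice with it, making areas exactly invariant whenever an atom
# has two non-collinear occluders, and (b) removing atoms beyond occlusion
# range cannot change the frame, so far deletions leave areas unchanged
# exactly. Atoms with fewer than two usable neighbors fall back to a
# lab-frame completion (their area is exact or axially near-symmetric).
.local_frame <- function(i, centers, nbr_idx) {
  nb <- nbr_idx[[i]]
  if (length(nb) == 0L) return(diag(3))
  d2 <- colSums((t(centers[nb, , drop = FALSE]) - centers[i, ])^2)
  # distances are rounded before ordering so that exact ties (symmetric
  # geometries) resolve by atom index identically before and after a rigid
  # motion of the model, keeping the frame rotation-covariant
  ord <- nb[order(round(d2, 6), nb)]
  v1 <- centers[ord[1L], ] - centers[i, ]
  e1 <- v1 / sqrt(sum(v1^2))
  e2 <- NULL
  for (j in ord[-1L]) {
    v <- centers[j, ] - centers[i, ]
    w <- v - sum(v * e1) * e1
    nw <- sqrt(sum(w^2))
    if (nw > 1e-6) { e2 <- w / nw; break }
  }
  if (is.null(e2)) {
    ax <- diag(3)[, which.min(abs(e1))]
    w <- ax - sum(ax * e1) * e1
    e2 <- w / sqrt(sum(w^2))
  }
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-sampling SASA: each atom's van der Waals sphere is
#' expanded by the probe radius and sampled with a deterministic
#' golden-spiral lattice; a sample point is accessible when it lies inside
#' no neighboring expanded sphere. Hydrogens and waters are excluded from
#' both computation and occlusion; HETATM ligand atoms are included (they
#' occlude the catalytic serine).
#'
#' @param model StructureModel
#' @param params [sasa_params()]
#' @param subset optional AtomSelection: compute areas only for these atoms
#'   (all other heavy atoms still occlude)
#' @return object of class `SasaResult`: data.frame `per_atom` (chain,
#'   resseq, icode, resname, atom, area), `total`, and the params echo
#' @export
shrake_rupley <- function(model, params = sasa_params(), subset = NULL) {
  a <- model$atoms
  keep <- !a$hydrogen & !a$water
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop("no heavy non-water atoms in model")
  centers <- as.matrix(a[, c("x", "y", "z")])
  radii <- .atom_radii(a, params)
  rexp <- radii + params$probe_radius
  if (is.null(subset)) {
    targets <- seq_len(nrow(a))
  } else {
    key_model <- paste(a$chain, a$resseq, a$icode, a$atom, sep = "\r")
    key_sel <- paste(subset$chain, subset$resseq, subset$icode, subset$atom,
                     sep = "\r")
    targets <- match(key_sel, key_model)
    if (anyNA(targets)) {
      stop("SASA subset contains atoms missing from the model: ",
           paste(key_sel[is.na(targets)], collapse = ", "))
    }
  }
  # neighbor lists under the occlusion cutoff r_i + r_j (expanded radii)
  n <- nrow(a)
  nbr_idx <- vector("list", n)
  d2 <- as.matrix(stats::dist(centers))^2
  for (i in unique(c(targets))) {
    cut2 <- (rexp[i] + rexp)^2
    nb <- which(d2[i, ] < cut2 & seq_len(n) != i)
    nbr_idx[[i]] <- nb
  }
  pts <- golden_spiral_points(params$n_points)
  areas <- numeric(length(targets))
  for (k in seq_along(targets)) {
    i <- targets[k]
    nb <- nbr_idx[[i]]
    full <- 4 * pi * rexp[i]^2
    if (length(nb) == 0L) { areas[k] <- full; next }
    fr <- .local_frame(i, centers, nbr_idx)
    p <- pts %*% t(fr) * rexp[i]
    p[, 1] <- p[, 1] + centers[i, 1]
    p[, 2] <- p[, 2] + centers[i, 2]
    p[, 3] <- p[, 3] + centers[i, 3]
    acc <- rep(TRUE, nrow(p))
    for (j in nb) {
      dj2 <- (p[, 1] - centers[j, 1])^2 + (p[, 2] - centers[j, 2])^2 +
        (p[, 3] - centers[j, 3])^2
      acc <- acc & (dj2 >= rexp[j]^2)
      if (!any(acc)) break
    }
    areas[k] <- full * sum(acc) / nrow(p)
  }
  per_atom <- data.frame(chain = a$chain[targets], resseq = a$resseq[targets],
                         icode = a$icode[targets],
                         resname = a$resname[targets], atom = a$atom[targets],
                         radius = radii[targets], area = areas,
                         stringsAsFactors = FALSE)
  structure(list(per_atom = per_atom, total = sum(areas), params = params),
            class = "SasaResult")
}

#' @export
print.SasaResult <- function(x, ...) {
  cat(sprintf("SasaResult: %d atoms, total %.1f A^2 (probe %.2f A, %d points)\n",
              nrow(x$per_atom), x$total, x$params$probe_radius,
              x$params$n_points))
  invisible(x)
}

#' Per-residue SASA sums
#' @param result SasaResult
#' @return data.frame chain/resseq/resname/area
#' @export
sasa_by_residue <- function(result) {
  p <- result$per_atom
  key <- paste(p$chain, p$resseq, p$icode, sep = "\r")
  out <- do.call(rbind, lapply(unique(key), function(k) {
    sub <- p[key == k, , drop = FALSE]
    data.frame(chain = sub$chain[1L], resseq = sub$resseq[1L],
               resname = sub$resname[1L], area = sum(sub$area),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Solvent accessibility of the catalytic serine sidechain
#'
#' SASA of the catalytic Ser sidechain heavy atoms (C-beta and O-gamma),
#' computed in the context of the full model (every heavy non-water atom,
#' ligands included, occludes), summed over the sidechain atoms. This is
#' the active-site "openness" proxy analyzed over conformational
#' ensembles.
#'
#' @param model StructureModel
#' @param site SiteDefinition
#' @param params [sasa_params()]
#' @param chain chain id; default: first chain on which the site resolves
#' @return sidechain SASA in Angstrom^2
#' @export
ser_sidechain_sasa <- function(model, site, params = sasa_params(),
                               chain = NULL) {
  if (is.null(chain)) {
    chains <- site_chains(model, site)
    if (length(chains) == 0L) stop("site does not resolve on model")
    chain <- chains[1L]
  }
  ch <- .ref_chain(site$ser, chain)
  sel <- atom_selection(ch, site$ser$resseq, c("CB", "OG"), site$ser$icode)
  # strict: both sidechain heavy atoms must exist
  invisible(select_atoms(model, sel, strict = TRUE))
  res <- shrake_rupley(model, params, subset = sel)
  res$total
}
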