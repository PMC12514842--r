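#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state,
#' so generators are deterministic per seed without clobbering the session.
#'
#' @param seed integer seed
#' @param code expression
#' @return value of `code`
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  code
}

#' Uniformly random proper rotation matrix
#' @param seed optional seed for reproducibility
#' @return 3 x 3 rotation matrix with determinant +1
#' @export
random_rotation <- function(seed = NULL) {
  gen <- function() {
    m <- matrix(stats::rnorm(9), 3, 3)
    q <- qr(m)
    r <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
    if (det(r) < 0) r[, 1] <- -r[, 1]
    r
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# residue layout of the toy hydrolase chain; numbering echoes nothing real,
# the roles do: a distal oxyanion Gly donor inside the oxyanion loop, a
# second donor adjacent to the catalytic Ser, core segments away from both
# loops so planted loop motions never pollute the core fit.
.toy_sequence <- c("ALA", "ALA", "PRO", "GLY", "ALA", "ALA", "SER",
                   "HIS", "ALA", "ALA", "HIS", "ALA", "ASP", "ALA")
.toy_roles <- list(
  donor_distal = 4L, donor_second = 8L, ser = 7L, his = 11L, asp = 13L,
  oxyanion_loop = c(3L, 6L), his_loop = c(11L, 12L),
  core = list(c(1L, 2L), c(9L, 10L), c(14L, 14L))
)

.toy_chain_atoms <- function(chain_id = "A") {
  # backbone follows a gentle in-plane arc (0.25 rad turn per residue) so
  # the triad forms a genuine, non-degenerate triangle; with N and C offset
  # 1.5 A along each residue's own tangent, the C(k)-N(k+1) peptide-like
  # link comes out at ~1.49 A, inside the 1.2-1.6 A bonded window
  nvec <- c(0, 0, 1)
  n_res <- length(.toy_sequence)
  theta <- 0.25
  tangents <- lapply(0:n_res, function(k) c(cos(k * theta), sin(k * theta), 0))
  ca <- vector("list", n_res)
  ca[[1]] <- c(4.4, 0, 0)
  for (k in seq_len(n_res - 1L)) ca[[k + 1L]] <- ca[[k]] + 4.4 * tangents[[k]]
  rows <- list()
  add <- function(res, resname, atom, element, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain_id, resseq = res, icode = "", resname = resname,
      atom = atom, altloc = "", x = xyz[1], y = xyz[2], z = xyz[3],
      occ = 1, b = 0, element = element, het = FALSE,
      hydrogen = FALSE, water = FALSE, stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_res)) {
    resname <- .toy_sequence[k]
    t_in <- tangents[[k]]       # residue tangent (CA(k) -> CA(k+1))
    add(k, resname, "N", "N", ca[[k]] - 1.5 * t_in)
    add(k, resname, "CA", "C", ca[[k]])
    add(k, resname, "C", "C", ca[[k]] + 1.5 * t_in)
    add(k, resname, "O", "O", ca[[k]] + 1.5 * t_in + 1.23 * nvec)
    if (resname != "GLY") {
      cb <- ca[[k]] - 1.53 * nvec
      add(k, resname, "CB", "C", cb)
      if (resname == "SER") add(k, resname, "OG", "O", cb + c(0, 0.71, -1.23))
      if (resname == "ASP") add(k, resname, "OD1", "O", cb + c(0, -0.71, -1.23))
    }
  }
  do.call(rbind, rows)
}

.d2_rotations <- list(
  A = diag(3),
  B = diag(c(-1, -1, 1)),   # C2 about z
  C = diag(c(-1, 1, -1)),   # C2 about y
  D = diag(c(1, -1, -1))    # C2 about x
)

.toy_bond_pairs <- function(atoms) {
  # bonded pairs of the toy topology, as index pairs into `atoms`
  key <- paste(atoms$chain, atoms$resseq, atoms$atom, sep = "\r")
  idx <- function(ch, res, at) match(paste(ch, res, at, sep = "\r"), key)
  pairs <- list()
  for (ch in unique(atoms$chain)) {
    res_ids <- sort(unique(atoms$resseq[atoms$chain == ch & !atoms$het]))
    for (k in res_ids) {
      bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("CA", "CB"),
                    c("CB", "OG"), c("CB", "OD1"))
      for (b in bonds) {
        i <- idx(ch, k, b[1]); j <- idx(ch, k, b[2])
        if (!is.na(i) && !is.na(j)) pairs[[length(pairs) + 1L]] <- c(i, j)
      }
      if ((k + 1L) %in% res_ids) {
        i <- idx(ch, k, "C"); j <- idx(ch, k + 1L, "N")
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  do.call(rbind, pairs)
}

.validate_toy_geometry <- function(model) {
  atoms <- model$atoms[!model$atoms$het, , drop = FALSE]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  bonds <- .toy_bond_pairs(atoms)
  blen <- sqrt(rowSums((xyz[bonds[, 1], , drop = FALSE] -
                          xyz[bonds[, 2], , drop = FALSE])^2))
  if (any(blen < 1.2 | blen > 1.6)) {
    stop(sprintf("fixture bond length outside 1.2-1.6 A (%.2f)",
                 blen[which(blen < 1.2 | blen > 1.6)[1L]]))
  }
  # non-bonded clash check excluding 1-2 and 1-3 pairs of the bond graph
  n <- nrow(xyz)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excluded <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    one <- adj[[i]]
    two <- unique(unlist(adj[one]))
    excluded[i, c(i, one, two)] <- TRUE
  }
  d <- as.matrix(stats::dist(xyz))
  bad <- which(d < 2.0 & !excluded & upper.tri(d), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("fixture non-bonded clash: atoms %d-%d at %.2f A",
                 bad[1, 1], bad[1, 2], d[bad[1, 1], bad[1, 2]]))
  }
  invisible(TRUE)
}

.toy_site_definition <- function() {
  r <- .toy_roles
  site_definition(
    name = "toy-hydrolase",
    ser = residue_ref(r$ser, "SER"),
    his = residue_ref(r$his, "HIS"),
    asp = residue_ref(r$asp, "ASP"),
    oxyanion_donors = list(
      list(ref = residue_ref(r$donor_distal, "GLY"), atom = "N"),
      list(ref = residue_ref(r$donor_second, "HIS"), atom = "N")
    ),
    distal_donor_index = 1L,
    oxyanion_loop = list(chain = NA, start = r$oxyanion_loop[1],
                         end = r$oxyanion_loop[2]),
    his_loop = list(chain = NA, start = r$his_loop[1], end = r$his_loop[2]),
    core = lapply(r$core, function(seg) {
      list(chain = NA, start = seg[1], end = seg[2])
    }),
    ligand = list(ref = residue_ref(901L, "LIG"),
                  atoms = c("P1", "O1", "C1"))
  )
}

#' Generate a toy hydrolase fixture
#'
#' Builds a minimal, chemically plausible "hydrolase" with a labeled
#' catalytic triad (Ser/His/Asp), two oxyanion-hole backbone-N donors (a
#' distal Gly inside the oxyanion loop and a His adjacent to the catalytic
#' Ser), loop segments, and core segments disjoint from both loops.
#' Chains are replicated with D2 point-group symmetry, mimicking a
#' homotetramer. Bonded atoms sit 1.2-1.6 A apart and no non-bonded pair
#' (beyond 1-3 neighbors) is closer than 2.0 A; the generator validates
#' this and errors otherwise. Per seed the output is identical.
#'
#' @param seed integer seed (drives only the optional coordinate noise)
#' @param n_chains 1 to 4 chains
#' @param noise_sigma isotropic Gaussian coordinate noise in Angstrom,
#'   applied last (default 0)
#' @return list with `model` (StructureModel), `site` (SiteDefinition) and
#'   `truth` (per-chain d1/d2/d3 computed by direct arithmetic from the
#'   final coordinates)
#' @export
make_toy_hydrolase <- function(seed = 1L, n_chains = 4L, noise_sigma = 0) {
  if (n_chains < 1L || n_chains > 4L) stop("n_chains must be 1..4")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  chain_ids <- names(.d2_rotations)[seq_len(n_chains)]
  offset <- c(5, 6, 7)
  blocks <- lapply(chain_ids, function(ch) {
    a <- .toy_chain_atoms(ch)
    xyz <- as.matrix(a[, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, -offset) %*% t(.d2_rotations[[ch]])
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    a
  })
  atoms <- do.call(rbind, blocks)
  # plausibility is a property of the constructed geometry; validate before
  # the noise, which emulates model-building coordinate uncertainty
  .validate_toy_geometry(structure_model(atoms, id = "pre-noise"))
  if (noise_sigma > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(3L * nrow(atoms),
                                                 sd = noise_sigma),
                                    ncol = 3L))
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
  }
  model <- structure_model(atoms, id = sprintf("toy-%d", seed))
  site <- .toy_site_definition()
  r <- .toy_roles
  truth <- do.call(rbind, lapply(chain_ids, function(ch) {
    g <- function(res, at) {
      a <- model$atoms
      i <- which(a$chain == ch & a$resseq == res & a$atom == at)
      c(a$x[i], a$y[i], a$z[i])
    }
    data.frame(chain = ch,
               d1 = sqrt(sum((g(r$ser, "CA") - g(r$his, "CA"))^2)),
               d2 = sqrt(sum((g(r$ser, "CA") - g(r$donor_distal, "N"))^2)),
               d3 = sqrt(sum((g(r$donor_distal, "N") - g(r$his, "CA"))^2)),
               stringsAsFactors = FALSE)
  }))
  list(model = model, site = site, truth = truth)
}

.add_toy_ligand <- function(model, site) {
  a <- model$atoms
  blocks <- list(a)
  for (ch in site_chains(model, site)) {
    og <- select_atoms(model, atom_selection(ch, site$ser$resseq, "OG"))[1L, ]
    cb <- select_atoms(model, atom_selection(ch, site$ser$resseq, "CB"))[1L, ]
    u <- og - cb; u <- u / sqrt(sum(u^2))
    p1 <- og + 3.0 * u
    # O1 and C1 at bonded offsets from P1 along directions moving with the
    # chain frame (u), so the ligand is rigid under chain placement
    w <- c(u[2], -u[1], 0); nw <- sqrt(sum(w^2))
    if (nw < 1e-6) { w <- c(1, 0, 0); nw <- 1 }
    w <- w / nw
    o1 <- p1 + 1.45 * w
    c1 <- p1 + 1.50 * u
    lig <- data.frame(
      chain = ch, resseq = 901L, icode = "", resname = "LIG",
      atom = c("P1", "O1", "C1"), altloc = "",
      x = c(p1[1], o1[1], c1[1]),
      y = c(p1[2], o1[2], c1[2]),
      z = c(p1[3], o1[3], c1[3]),
      occ = 1, b = 0, element = c("P", "O", "C"), het = TRUE,
      hydrogen = FALSE, water = FALSE, stringsAsFactors = FALSE)
    blocks[[length(blocks) + 1L]] <- lig
  }
  structure_model(do.call(rbind, blocks), id = paste0(model$id, "-holo"))
}

#' Derive a holo fixture from an apo fixture
#'
#' Emulates ligand-binding rearrangement with known ground truth: a ligand
#' is planted near each catalytic Ser O-gamma, the oxyanion-loop atoms are
#' displaced by exactly `loop_shift` Angstrom, each atom along its own
#' direction toward the chain's ligand centroid (so the planted
#' displacement magnitude and "toward" classification are exact), then the
#' whole model undergoes a rigid motion, then optional Gaussian noise.
#' Planted truths are attached as attribute `"planted"`.
#'
#' @param apo fixture list from [make_toy_hydrolase()] (or a compatible
#'   `list(model, site)`)
#' @param loop_shift planted displacement magnitude in Angstrom (default 0)
#' @param motion planted whole-model rigid motion: a [rigid_transform()], or
#'   NULL for a seed-derived random one, or FALSE for none
#' @param add_ligand plant the ligand residue (default TRUE)
#' @param noise_sigma isotropic coordinate noise applied last (default 0)
#' @param seed seed for the random motion and the noise
#' @return holo StructureModel with attribute `"planted"` (list: transform,
#'   shift atoms, magnitude, per-chain ligand centroids in the pre-motion
#'   frame)
#' @export
make_holo_from_apo <- function(apo, loop_shift = 0, motion = NULL,
                               add_ligand = TRUE, noise_sigma = 0,
                               seed = 1L) {
  model <- apo$model; site <- apo$site
  holo <- if (add_ligand) .add_toy_ligand(model, site) else model
  chains <- site_chains(model, site)
  shift_rows <- NULL
  centroids <- list()
  if (loop_shift > 0) {
    loop <- site$oxyanion_loop
    for (ch in chains) {
      cen <- .ligand_centroid(holo, site, ch)
      if (is.null(cen)) {  # no ligand: shift toward the Ser O-gamma
        cen <- select_atoms(holo, atom_selection(ch, site$ser$resseq,
                                                 "OG"))[1L, ]
      }
      centroids[[ch]] <- cen
      a <- holo$atoms
      idx <- which(a$chain == ch & a$resseq >= loop$start &
                     a$resseq <= loop$end & !a$het)
      for (i in idx) {
        x <- c(a$x[i], a$y[i], a$z[i])
        u <- cen - x; u <- u / sqrt(sum(u^2))
        x <- x + loop_shift * u
        holo$atoms$x[i] <- x[1]; holo$atoms$y[i] <- x[2]
        holo$atoms$z[i] <- x[3]
      }
      shift_rows <- rbind(shift_rows, data.frame(
        chain = ch, resseq = holo$atoms$resseq[idx],
        atom = holo$atoms$atom[idx], magnitude = loop_shift,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(motion)) {
    motion <- with_seed(seed, {
      rigid_transform(random_rotation(), stats::rnorm(3, sd = 5))
    })
  }
  if (!identical(motion, FALSE)) {
    holo <- transform_model(holo, motion)
  } else {
    motion <- NULL
  }
  if (noise_sigma > 0) {
    noise <- with_seed(seed + 104729L,
                       matrix(stats::rnorm(3L * nrow(holo$atoms),
                                           sd = noise_sigma), ncol = 3L))
    holo$atoms$x <- holo$atoms$x + noise[, 1]
    holo$atoms$y <- holo$atoms$y + noise[, 2]
    holo$atoms$z <- holo$atoms$z + noise[, 3]
  }
  attr(holo, "planted") <- list(transform = motion,
                                shift = shift_rows,
                                loop_shift = loop_shift,
                                ligand_centroids = centroids,
                                noise_sigma = noise_sigma)
  holo
}

#' Pseudo-atom sphere system for SASA oracles
#'
#' Builds a model of bare spheres with exactly the requested radii; the
#' radii are returned as an atom-name override table for [sasa_params()].
#'
#' @param radii numeric vector of sphere radii, Angstrom
#' @param centers n x 3 matrix of centers
#' @return list with `model` and `radii_override`
#' @export
make_sphere_system <- function(radii, centers) {
  centers <- as.matrix(centers)
  if (length(radii) != nrow(centers)) stop("radii/centers length mismatch")
  nm <- sprintf("X%d", seq_along(radii))
  atoms <- data.frame(
    chain = "S", resseq = seq_along(radii), icode = "", resname = "SPH",
    atom = nm, altloc = "", x = centers[, 1], y = centers[, 2],
    z = centers[, 3], occ = 1, b = 0, element = "X", het = TRUE,
    hydrogen = FALSE, water = FALSE, stringsAsFactors = FALSE)
  list(model = structure_model(atoms, id = "spheres"),
       radii_override = setNames(radii, nm))
}

.place_occluder_cage <- function(model, site, chain, dist) {
  og <- select_atoms(model, atom_selection(chain, site$ser$resseq, "OG"))[1L, ]
  cb <- select_atoms(model, atom_selection(chain, site$ser$resseq, "CB"))[1L, ]
  mid <- (og + cb) / 2
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  cage <- data.frame(
    chain = chain, resseq = 950L + seq_len(nrow(dirs)), icode = "",
    resname = "CAG", atom = "C1", altloc = "",
    x = mid[1] + dist * dirs[, 1], y = mid[2] + dist * dirs[, 2],
    z = mid[3] + dist * dirs[, 3], occ = 1, b = 0, element = "C",
    het = TRUE, hydrogen = FALSE, water = FALSE, stringsAsFactors = FALSE)
  structure_model(rbind(model$atoms, cage), id = model$id)
}

.cage_sasa <- function(base, site, chain, dist, params) {
  m <- .place_occluder_cage(base, site, chain, dist)
  ser_sidechain_sasa(m, site, params = params, chain = chain)
}

#' Generate a conformational ensemble with planted structure
#'
#' Emulates a dissected monomer trajectory alternating between an open and
#' a closed state. Cluster structure is planted on the protein: the closed
#' state's oxyanion-loop is displaced so that the open/closed main-chain+CB
#' RMSD after fitting matches `inter_state_rmsd`, while per-frame jitter
#' keeps intra-state RMSD far below the clustering cutoff. Catalytic-Ser
#' sidechain SASA bimodality is planted exactly: per frame a target SASA is
#' drawn from the configured two-normal mixture and a cage of occluding
#' pseudo-atoms (HETATM, hence invisible to the protein-only clustering
#' selection) is positioned by root-finding so the measured sidechain SASA
#' hits the target to within the lattice quantization (~0.1 A^2).
#'
#' @param seed integer seed
#' @param n_frames number of frames (default 200)
#' @param means,sigmas,weights two-component SASA mixture truth in
#'   Angstrom^2; defaults are the compact (~9) and relaxed (~29.5) states
#'   with sigma 0.5/0.6 at equal weight
#' @param inter_state_rmsd planted open/closed fitted RMSD over the
#'   clustering selection, Angstrom (default 2.5)
#' @param jitter_sigma within-state coordinate jitter, Angstrom
#' @param params SASA parameters used for calibration (use the same when
#'   analyzing)
#' @return list with `ensemble`, `site`, and `truth` (state labels, target
#'   SASA values, mixture parameters)
#' @export
make_ensemble <- function(seed = 1L, n_frames = 200L,
                          means = c(9.0, 29.5), sigmas = c(0.5, 0.6),
                          weights = c(0.5, 0.5), inter_state_rmsd = 2.5,
                          jitter_sigma = 0.02, params = sasa_params()) {
  stopifnot(length(means) == 2L, length(sigmas) == 2L,
            abs(sum(weights) - 1) < 1e-9)
  base <- make_toy_hydrolase(seed = seed, n_chains = 1L)
  open_model <- base$model; site <- base$site
  sel_atoms <- c("N", "CA", "C", "O", "CB")
  # closed template: displace the oxyanion loop toward the Ser O-gamma,
  # scaling the magnitude until the fitted selection RMSD hits the target
  loop <- site$oxyanion_loop
  og <- select_atoms(open_model, atom_selection("A", site$ser$resseq, "OG"))[1L, ]
  a <- open_model$atoms
  loop_idx <- which(a$resseq >= loop$start & a$resseq <= loop$end & !a$het)
  loop_cen <- colMeans(as.matrix(a[loop_idx, c("x", "y", "z")]))
  u <- og - loop_cen; u <- u / sqrt(sum(u^2))
  closed_at <- function(delta) {
    m <- open_model
    m$atoms$x[loop_idx] <- m$atoms$x[loop_idx] + delta * u[1]
    m$atoms$y[loop_idx] <- m$atoms$y[loop_idx] + delta * u[2]
    m$atoms$z[loop_idx] <- m$atoms$z[loop_idx] + delta * u[3]
    m
  }
  fitted_rmsd <- function(delta) {
    ens2 <- as_ensemble(list(open_model, closed_at(delta)))
    pairwise_rmsd_matrix(ens2, clustering_params(atoms = sel_atoms))[1, 2]
  }
  delta <- inter_state_rmsd
  for (i in 1:4) {
    r <- fitted_rmsd(delta)
    delta <- delta * inter_state_rmsd / r
  }
  closed_model <- closed_at(delta)
  # component 1 (compact, low SASA) lives on the closed template whose
  # forward-shifted loop crowds the Ser; component 2 (relaxed, high SASA)
  # on the open template, so every drawn target is geometrically reachable
  templates <- list(closed_model, open_model)
  with_seed(seed, {
    states <- sample.int(2L, n_frames, replace = TRUE, prob = weights)
    targets <- stats::rnorm(n_frames, means[states], sigmas[states])
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      m <- templates[[states[f]]]
      jit <- matrix(stats::rnorm(3L * nrow(m$atoms), sd = jitter_sigma),
                    ncol = 3L)
      m$atoms$x <- m$atoms$x + jit[, 1]
      m$atoms$y <- m$atoms$y + jit[, 2]
      m$atoms$z <- m$atoms$z + jit[, 3]
      m$id <- sprintf("frame-%d", f)
      # position the occluder cage to hit the drawn SASA target
      f_lo <- .cage_sasa(m, site, "A", 1.5, params)
      f_hi <- .cage_sasa(m, site, "A", 14, params)
      tgt <- min(max(targets[f], f_lo + 0.2), f_hi - 0.2)
      targets[f] <- tgt
      root <- stats::uniroot(function(d) {
        .cage_sasa(m, site, "A", d, params) - tgt
      }, lower = 1.5, upper = 14, tol = 1e-3)
      frames[[f]] <- .place_occluder_cage(m, site, "A", root$root)
    }
    list(ensemble = as_ensemble(frames), site = site,
         truth = list(states = states, targets = targets, means = means,
                      sigmas = sigmas, weights = weights, delta = delta,
                      inter_state_rmsd = inter_state_rmsd))
  })
}

#' Write a fixture as PDB plus a JSON ground-truth sidecar
#'
#' @param model StructureModel (planted truths read from the `"planted"`
#'   attribute when present)
#' @param path output PDB path; the sidecar is written next to it with
#'   extension `.truth.json`
#' @return `path`, invisibly
#' @export
write_fixture <- function(model, path) {
  write_pdb(model, path)
  planted <- attr(model, "planted")
  truth <- list(id = model$id)
  if (!is.null(planted)) {
    truth$loop_shift <- planted$loop_shift
    truth$noise_sigma <- planted$noise_sigma
    if (!is.null(planted$transform)) {
      truth$transform <- transform_to_list(planted$transform)
    }
    if (!is.null(planted$shift)) truth$shift <- planted$shift
  }
  jsonlite::write_json(truth, sub("\\.pdb$", ".truth.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
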