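#' Reference to a residue
#'
#' Residue references use author-assigned numbering (the numbering cited in
#' the structural literature, e.g. Ser587 of porcine acylpeptide
#' hydrolase). `chain = NA` means "every chain of the model": site
#' definitions are written once per enzyme and applied to each monomer of
#' an oligomer.
#'
#' @param resseq author residue number
#' @param resname optional 3-letter code, checked when resolving if given
#' @param chain chain id or NA for all chains
#' @param icode insertion code, default blank
#' @return list of class `ResidueRef`
#' @export
residue_ref <- function(resseq, resname = NULL, chain = NA_character_,
                        icode = "") {
  structure(list(resseq = as.integer(resseq),
                 resname = if (is.null(resname)) NULL else toupper(resname),
                 chain = chain, icode = icode),
            class = "ResidueRef")
}

.ref_chain <- function(ref, chain) {
  if (is.na(ref$chain)) chain else ref$chain
}

#' Declarative description of one enzyme's catalytic machinery
#'
#' Holds the catalytic triad, the ordered oxyanion-hole donor atoms (the
#' backbone amide nitrogens for canonical alpha/beta hydrolases; a tyrosine
#' hydroxyl oxygen for DPP4-style sites), which donor is "distal" (used as
#' the heteroatom of the d2/d3 triangle sides), the oxyanion- and His-loop
#' segments, the core segments used for domain superposition, and the
#' optional ligand key atoms used to orient shift directions.
#'
#' @param name enzyme label
#' @param ser,his,asp [residue_ref()]s of the catalytic triad
#' @param oxyanion_donors list of `list(ref = residue_ref, atom = name)`
#' @param distal_donor_index index into `oxyanion_donors` of the distal
#'   donor (default 1)
#' @param oxyanion_loop,his_loop segment specs `list(chain, start, end)`
#'   with `chain = NA` meaning per-chain application
#' @param core list of segment specs for the superposition core
#' @param ligand optional `list(ref = residue_ref, atoms = c(...))`
#' @return object of class `SiteDefinition`
#' @export
site_definition <- function(name, ser, his, asp, oxyanion_donors,
                            distal_donor_index = 1L,
                            oxyanion_loop = NULL, his_loop = NULL,
                            core = NULL, ligand = NULL) {
  triad <- list(ser, his, asp)
  key <- vapply(triad, function(r) paste(r$chain, r$resseq, r$icode),
                character(1))
  if (anyDuplicated(key)) stop("catalytic triad residues must be distinct")
  if (distal_donor_index < 1L || distal_donor_index > length(oxyanion_donors)) {
    stop("distal_donor_index out of range")
  }
  if (!is.null(oxyanion_loop) && !is.null(his_loop)) {
    if (oxyanion_loop$start <= his_loop$end && his_loop$start <= oxyanion_loop$end) {
      stop("oxyanion loop and His loop segments overlap")
    }
  }
  structure(list(name = name, ser = ser, his = his, asp = asp,
                 oxyanion_donors = oxyanion_donors,
                 distal_donor_index = as.integer(distal_donor_index),
                 oxyanion_loop = oxyanion_loop, his_loop = his_loop,
                 core = core, ligand = ligand),
            class = "SiteDefinition")
}

#' @export
print.SiteDefinition <- function(x, ...) {
  donor <- x$oxyanion_donors[[x$distal_donor_index]]
  cat(sprintf(
    "SiteDefinition '%s': Ser%d / His%d / Asp%d; distal donor %s%d:%s\n",
    x$name, x$ser$resseq, x$his$resseq, x$asp$resseq,
    if (is.null(donor$ref$resname)) "" else donor$ref$resname,
    donor$ref$resseq, donor$atom))
  invisible(x)
}

.site_core_segments <- function(site, chain) {
  lapply(site$core, function(seg) {
    list(chain = if (is.null(seg$chain) || is.na(seg$chain)) chain else seg$chain,
         start = seg$start, end = seg$end)
  })
}

#' Chains of a model on which a site resolves
#' @param model StructureModel
#' @param site SiteDefinition
#' @return character vector of chain ids containing the full triad
#' @export
site_chains <- function(model, site) {
  chains <- model_chains(model)
  keep <- vapply(chains, function(ch) {
    ok <- TRUE
    for (r in list(site$ser, site$his, site$asp)) {
      a <- model$atoms
      hit <- a$chain == .ref_chain(r, ch) & a$resseq == r$resseq &
        a$icode == r$icode
      ok <- ok && any(hit)
    }
    ok
  }, logical(1))
  chains[keep]
}

#' Distance between two named atoms
#'
#' @param model StructureModel
#' @param a,b `list(ref = residue_ref, atom = name)` pairs; `chain` fills
#'   chain-less refs
#' @param chain chain applied to refs with `chain = NA`
#' @return Euclidean distance in Angstrom
#' @export
atom_distance <- function(model, a, b, chain = NA_character_) {
  get_xyz <- function(p) {
    ch <- .ref_chain(p$ref, chain)
    if (is.na(ch)) stop("no chain given for a chain-less residue reference")
    sel <- atom_selection(ch, p$ref$resseq, p$atom, p$ref$icode)
    select_atoms(model, sel, strict = TRUE)[1L, ]
  }
  sqrt(sum((get_xyz(a) - get_xyz(b))^2))
}

#' The d1/d2/d3 active-site triangle
#'
#' Describes the size of a serine hydrolase active site with three
#' distances forming a triangle: d1 between the C-alpha atoms of the
#' catalytic Ser and His; d2 between C-alpha(Ser) and the distal
#' oxyanion-hole donor heteroatom (the backbone N of the distal donor
#' residue for canonical sites, a configured sidechain O for DPP4-style
#' sites); and d3 between that donor heteroatom and C-alpha(His). Values
#' are computed per chain and averaged (arithmetic mean with sample SD)
#' across the chains on which the site resolves.
#'
#' @param model StructureModel
#' @param site SiteDefinition
#' @return object of class `TriadTriangle` with elements `per_chain`
#'   (data.frame chain/d1/d2/d3), `mean` and `sd` (named length-3 vectors)
#' @export
triad_triangle <- function(model, site) {
  chains <- site_chains(model, site)
  if (length(chains) == 0L) {
    stop("triad does not resolve on any chain of '", model$id, "'")
  }
  donor <- site$oxyanion_donors[[site$distal_donor_index]]
  rows <- lapply(chains, function(ch) {
    ser_ca <- list(ref = site$ser, atom = "CA")
    his_ca <- list(ref = site$his, atom = "CA")
    d1 <- atom_distance(model, ser_ca, his_ca, chain = ch)
    d2 <- atom_distance(model, ser_ca, donor, chain = ch)
    d3 <- atom_distance(model, donor, his_ca, chain = ch)
    data.frame(chain = ch, d1 = d1, d2 = d2, d3 = d3,
               stringsAsFactors = FALSE)
  })
  per_chain <- do.call(rbind, rows)
  for (i in seq_len(nrow(per_chain))) {
    d <- as.numeric(per_chain[i, c("d1", "d2", "d3")])
    if (any(d <= 0) || any(d > sum(d) - d)) {
      stop("degenerate triangle on chain ", per_chain$chain[i])
    }
  }
  m <- colMeans(per_chain[, c("d1", "d2", "d3")])
  s <- if (nrow(per_chain) > 1L) {
    apply(per_chain[, c("d1", "d2", "d3")], 2, sd)
  } else {
    c(d1 = NA_real_, d2 = NA_real_, d3 = NA_real_)
  }
  structure(list(site = site$name, per_chain = per_chain,
                 mean = m, sd = s),
            class = "TriadTriangle")
}

#' @export
print.TriadTriangle <- function(x, ...) {
  cat(sprintf("TriadTriangle [%s] over %d chain(s):\n", x$site,
              nrow(x$per_chain)))
  cat(sprintf("  d1 = %.2f  d2 = %.2f  d3 = %.2f (A, chain mean)\n",
              x$mean["d1"], x$mean["d2"], x$mean["d3"]))
  invisible(x)
}

#' Classify a donor-acceptor distance as hydrogen bond or not
#'
#' Heavy-atom donor-acceptor criterion with an inclusive cutoff (default
#' 3.5 A). No angular term is applied because the structures this package
#' targets (cryo-EM depositions) carry no hydrogens.
#'
#' @param distance distance(s) in Angstrom, >= 0
#' @param cutoff inclusive cutoff in Angstrom
#' @return character vector, `"bond"` or `"too_far"`
#' @export
hbond_classify <- function(distance, cutoff = 3.5) {
  if (any(distance < 0)) stop("negative distance")
  if (cutoff <= 0) stop("cutoff must be positive")
  ifelse(distance <= cutoff, "bond", "too_far")
}

.ligand_centroid <- function(model, site, chain) {
  if (is.null(site$ligand)) return(NULL)
  ch <- .ref_chain(site$ligand$ref, chain)
  sel <- atom_selection(ch, site$ligand$ref$resseq, site$ligand$atoms,
                        site$ligand$ref$icode)
  xyz <- select_atoms(model, sel, strict = FALSE)
  if (nrow(xyz) == 0L) return(NULL)
  colMeans(xyz)
}

#' Apo-to-holo loop shift in the core-fitted frame
#'
#' Measures, atom by atom, how far named atoms move between a ligand-free
#' and a ligand-bound structure after the holo model has been superposed
#' onto the apo model chain-by-chain on the core segments (see
#' [core_superpose()]). Each displacement is classified as `"toward"` or
#' `"away"` from a reference point: the centroid of the configured ligand
#' key atoms in the (fitted) holo structure when a ligand is present,
#' otherwise the holo catalytic Ser O-gamma. Per-chain values are averaged
#' with sample SD; display values round to 0.1 A, raw values are retained.
#'
#' @param apo,holo StructureModels
#' @param site SiteDefinition (supplies the core segments and reference
#'   point)
#' @param atoms list of `list(ref = residue_ref, atom = name)` to measure
#' @param chain_pairing passed to [core_superpose()]
#' @return object of class `ShiftReport`: data.frame `per_atom` with one
#'   row per (atom, chain), plus `summary` with chain mean and SD per atom
#' @export
loop_shift <- function(apo, holo, site, atoms, chain_pairing = "by_id") {
  chains <- site_chains(apo, site)
  if (length(chains) == 0L) stop("site does not resolve on apo model")
  core <- unlist(lapply(chains, function(ch) .site_core_segments(site, ch)),
                 recursive = FALSE)
  fit <- core_superpose(holo, apo, core, chain_pairing = chain_pairing)
  holo_fit <- fit$model
  rows <- list()
  for (ch in chains) {
    mob_ch <- fit$pairing[[ch]]
    refpt <- .ligand_centroid(holo_fit, site, mob_ch)
    has_ref <- !is.null(refpt)
    if (!has_ref) {
      og <- try(select_atoms(
        holo_fit, atom_selection(mob_ch, site$ser$resseq, "OG",
                                 site$ser$icode)), silent = TRUE)
      if (!inherits(og, "try-error")) { refpt <- og[1L, ]; has_ref <- TRUE }
    }
    for (a in atoms) {
      sel_apo <- atom_selection(.ref_chain(a$ref, ch), a$ref$resseq, a$atom,
                                a$ref$icode)
      sel_holo <- atom_selection(.ref_chain(a$ref, mob_ch), a$ref$resseq,
                                 a$atom, a$ref$icode)
      x_apo <- select_atoms(apo, sel_apo, strict = TRUE)[1L, ]
      x_holo <- select_atoms(holo_fit, sel_holo, strict = TRUE)[1L, ]
      disp <- sqrt(sum((x_holo - x_apo)^2))
      dir <- "n/a"
      if (has_ref && disp > 1e-9) {
        d_apo <- sqrt(sum((x_apo - refpt)^2))
        d_holo <- sqrt(sum((x_holo - refpt)^2))
        dir <- if (d_holo < d_apo) "toward" else "away"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resseq = a$ref$resseq,
        resname = if (is.null(a$ref$resname)) NA_character_ else a$ref$resname,
        atom = a$atom, displacement = disp, direction = dir,
        core_rmsd = fit$rmsd[[ch]], stringsAsFactors = FALSE)
    }
  }
  per_atom <- do.call(rbind, rows)
  agg_key <- paste(per_atom$resseq, per_atom$atom)
  summary <- do.call(rbind, lapply(unique(agg_key), function(k) {
    sub <- per_atom[agg_key == k, , drop = FALSE]
    data.frame(resseq = sub$resseq[1L], atom = sub$atom[1L],
               mean = mean(sub$displacement),
               sd = if (nrow(sub) > 1L) sd(sub$displacement) else NA_real_,
               display = round(mean(sub$displacement), 1L),
               direction = {
                 dirs <- unique(sub$direction[sub$direction != "n/a"])
                 if (length(dirs) == 1L) dirs else if (length(dirs) == 0L)
                   "n/a" else "mixed"
               },
               stringsAsFactors = FALSE)
  }))
  structure(list(per_atom = per_atom, summary = summary,
                 core_rmsd = fit$rmsd),
            class = "ShiftReport")
}

#' @export
print.ShiftReport <- function(x, ...) {
  cat("ShiftReport (chain-averaged displacements, A):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  res %d %-4s %.1f %s\n", s$resseq[i], s$atom[i],
                s$display[i], s$direction[i]))
  }
  invisible(x)
}

#' Apo/holo delta table of triangle statistics
#'
#' One row per structure pair with the apo, holo and signed holo - apo
#' values of d1/d2/d3; the numeric substrate of a cross-enzyme heatmap.
#' Column names are fixed: `label, d1_apo, d2_apo, d3_apo, d1_holo,
#' d2_holo, d3_holo, dd1, dd2, dd3`.
#'
#' @param entries list of `list(label, apo = TriadTriangle,
#'   holo = TriadTriangle)`
#' @return data.frame of class `DeltaTable`
#' @export
delta_table <- function(entries) {
  if (length(entries) == 0L) stop("empty entry list")
  rows <- lapply(entries, function(e) {
    a <- e$apo$mean; h <- e$holo$mean
    data.frame(label = e$label,
               d1_apo = a[["d1"]], d2_apo = a[["d2"]], d3_apo = a[["d3"]],
               d1_holo = h[["d1"]], d2_holo = h[["d2"]], d3_holo = h[["d3"]],
               dd1 = h[["d1"]] - a[["d1"]],
               dd2 = h[["d2"]] - a[["d2"]],
               dd3 = h[["d3"]] - a[["d3"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("DeltaTable", "data.frame")
  out
}
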