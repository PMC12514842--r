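#' Read a site-definition config file
#'
#' Site configs are declarative JSON documents, one per enzyme, holding the
#' catalytic triad, oxyanion donors, distal donor index, loop segments,
#' core segments, optional ligand key atoms, and free-text provenance
#' notes. Curated configs ship under `inst/extdata/sites/` (see
#' [shipped_site_config()]).
#'
#' @param path JSON file path
#' @return SiteDefinition (provenance notes in attribute `"provenance"`)
#' @export
read_site_config <- function(path) {
  if (!file.exists(path)) stop("cannot read site config: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("name", "ser", "his", "asp", "oxyanion_donors")
  missing <- setdiff(need, names(doc))
  if (length(missing) > 0L) {
    stop("site config ", path, " lacks fields: ",
         paste(missing, collapse = ", "))
  }
  ref <- function(x) {
    residue_ref(x$resseq, resname = x$resname,
                chain = if (is.null(x$chain)) NA_character_ else x$chain,
                icode = if (is.null(x$icode)) "" else x$icode)
  }
  seg <- function(s) {
    if (is.null(s)) return(NULL)
    list(chain = if (is.null(s$chain)) NA_character_ else s$chain,
         start = as.integer(s$start), end = as.integer(s$end))
  }
  donors <- lapply(doc$oxyanion_donors, function(d) {
    list(ref = ref(d), atom = d$atom)
  })
  lig <- NULL
  if (!is.null(doc$ligand)) {
    lig <- list(ref = ref(doc$ligand),
                atoms = unlist(doc$ligand$atoms))
  }
  site <- site_definition(
    name = doc$name, ser = ref(doc$ser), his = ref(doc$his),
    asp = ref(doc$asp), oxyanion_donors = donors,
    distal_donor_index = if (is.null(doc$distal_donor_index)) 1L else
      as.integer(doc$distal_donor_index),
    oxyanion_loop = seg(doc$oxyanion_loop),
    his_loop = seg(doc$his_loop),
    core = if (is.null(doc$core)) NULL else lapply(doc$core, seg),
    ligand = lig)
  attr(site, "provenance") <- doc$provenance
  site
}

#' Write a SiteDefinition as a JSON config
#' @param site SiteDefinition
#' @param path output path
#' @param provenance optional notes (accessions the config applies to, how
#'   segment ranges were curated)
#' @return `path`, invisibly
#' @export
write_site_config <- function(site, path, provenance = NULL) {
  unref <- function(r) {
    out <- list(resseq = r$resseq)
    if (!is.null(r$resname)) out$resname <- r$resname
    if (!is.na(r$chain)) out$chain <- r$chain
    if (nzchar(r$icode)) out$icode <- r$icode
    out
  }
  unseg <- function(s) {
    if (is.null(s)) return(NULL)
    out <- list(start = s$start, end = s$end)
    if (!is.null(s$chain) && !is.na(s$chain)) out$chain <- s$chain
    out
  }
  doc <- list(
    name = site$name, ser = unref(site$ser), his = unref(site$his),
    asp = unref(site$asp),
    oxyanion_donors = lapply(site$oxyanion_donors, function(d) {
      c(unref(d$ref), list(atom = d$atom))
    }),
    distal_donor_index = site$distal_donor_index,
    oxyanion_loop = unseg(site$oxyanion_loop),
    his_loop = unseg(site$his_loop),
    core = if (is.null(site$core)) NULL else lapply(site$core, unseg))
  if (!is.null(site$ligand)) {
    doc$ligand <- c(unref(site$ligand$ref),
                    list(atoms = as.list(site$ligand$atoms)))
  }
  if (!is.null(provenance)) doc$provenance <- provenance
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Path of a shipped curated site config
#' @param name config name, e.g. `"papeh"`, `"ache"`, `"dpp4"`
#' @return file path inside the installed package
#' @export
shipped_site_config <- function(name) {
  p <- system.file("extdata", "sites", paste0(name, ".json"),
                   package = "sitegeom")
  if (!nzchar(p)) {
    stop("no shipped site config '", name, "'; available: ",
         paste(sub("\\.json$", "",
                   dir(system.file("extdata", "sites",
                                   package = "sitegeom"))),
               collapse = ", "))
  }
  p
}

.provenance <- function(inputs = character(0), config = NULL) {
  list(tool = "sitegeom",
       version = as.character(utils::packageVersion("sitegeom")),
       input_md5 = as.list(setNames(
         unname(tools::md5sum(inputs[file.exists(inputs)])),
         basename(inputs[file.exists(inputs)]))),
       config_md5 = if (is.null(config)) NULL else
         unname(tools::md5sum(config)))
}

#' Apo/holo comparison report
#'
#' Runs the full apo-versus-holo measurement: per-chain core superposition,
#' loop-shift report for the distal oxyanion donor backbone (N, CA) and
#' the catalytic His C-alpha, the d1/d2/d3 triangle of both structures,
#' and oxyanion H-bond classification of any configured ligand key-atom
#' contacts. Writes `shift.json`, `shift.csv`, `triangles.json` and
#' `delta.csv` under `out_dir`, each embedding tool version and input
#' checksums.
#'
#' @param apo_path,holo_path coordinate files (PDB or mmCIF)
#' @param site SiteDefinition or path to a site config
#' @param out_dir output directory (created), or NULL to skip writing
#' @param chain_pairing passed to [core_superpose()]
#' @param hbond_cutoff inclusive donor-acceptor cutoff, Angstrom
#' @return list with `shift` (ShiftReport), `apo_triangle`,
#'   `holo_triangle`, `delta` (DeltaTable), `contacts` (data.frame or NULL)
#' @export
run_compare <- function(apo_path, holo_path, site, out_dir = NULL,
                        chain_pairing = "by_id", hbond_cutoff = 3.5) {
  config_path <- NULL
  if (is.character(site)) { config_path <- site; site <- read_site_config(site) }
  apo <- parse_structure(apo_path)
  holo <- parse_structure(holo_path)
  donor <- site$oxyanion_donors[[site$distal_donor_index]]
  atoms <- list(list(ref = donor$ref, atom = "N"),
                list(ref = donor$ref, atom = "CA"),
                list(ref = site$his, atom = "CA"))
  shift <- loop_shift(apo, holo, site, atoms, chain_pairing = chain_pairing)
  tri_apo <- triad_triangle(apo, site)
  tri_holo <- triad_triangle(holo, site)
  delta <- delta_table(list(list(label = site$name, apo = tri_apo,
                                 holo = tri_holo)))
  contacts <- NULL
  if (!is.null(site$ligand)) {
    rows <- list()
    for (ch in site_chains(holo, site)) {
      for (d in site$oxyanion_donors) {
        for (la in site$ligand$atoms) {
          dd <- try(atom_distance(
            holo, list(ref = d$ref, atom = d$atom),
            list(ref = site$ligand$ref, atom = la), chain = ch),
            silent = TRUE)
          if (inherits(dd, "try-error")) next
          rows[[length(rows) + 1L]] <- data.frame(
            chain = ch, donor_resseq = d$ref$resseq, donor_atom = d$atom,
            ligand_atom = la, distance = dd,
            hbond = hbond_classify(dd, hbond_cutoff),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) > 0L) contacts <- do.call(rbind, rows)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- .provenance(c(apo_path, holo_path), config_path)
    jsonlite::write_json(
      list(provenance = prov, per_atom = shift$per_atom,
           summary = shift$summary, core_rmsd = as.list(shift$core_rmsd)),
      file.path(out_dir, "shift.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(shift$per_atom, file.path(out_dir, "shift.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(provenance = prov,
           apo = list(per_chain = tri_apo$per_chain,
                      mean = as.list(tri_apo$mean)),
           holo = list(per_chain = tri_holo$per_chain,
                       mean = as.list(tri_holo$mean))),
      file.path(out_dir, "triangles.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(delta), file.path(out_dir, "delta.csv"),
                     row.names = FALSE)
    if (!is.null(contacts)) {
      utils::write.csv(contacts, file.path(out_dir, "contacts.csv"),
                       row.names = FALSE)
    }
  }
  list(shift = shift, apo_triangle = tri_apo, holo_triangle = tri_holo,
       delta = delta, contacts = contacts)
}

#' Cross-enzyme panel of apo/holo triangle deltas
#'
#' Processes a manifest of structure pairs into one [delta_table()] CSV.
#' Failures are isolated per row: a bad entry is reported in the summary
#' without aborting the panel.
#'
#' @param manifest list of entries `list(label, apo, holo, site)` (site =
#'   SiteDefinition or config path), or a path to a JSON manifest with an
#'   `entries` array and optional `out_dir`
#' @param out_dir output directory for `panel.csv` + `panel_summary.json`
#' @return list with `table` (DeltaTable), `failures` (named list of error
#'   messages)
#' @export
run_panel <- function(manifest, out_dir = NULL) {
  manifest_path <- NULL
  if (is.character(manifest)) {
    manifest_path <- manifest
    doc <- jsonlite::read_json(manifest, simplifyVector = FALSE)
    if (is.null(out_dir)) out_dir <- doc$out_dir
    manifest <- doc$entries
  }
  if (length(manifest) == 0L) stop("empty manifest")
  labels <- vapply(manifest, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate manifest labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  entries <- list(); failures <- list()
  for (e in manifest) {
    res <- try({
      site <- if (is.character(e$site)) read_site_config(e$site) else e$site
      apo <- parse_structure(e$apo); holo <- parse_structure(e$holo)
      list(label = e$label, apo = triad_triangle(apo, site),
           holo = triad_triangle(holo, site))
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failures[[e$label]] <- conditionMessage(attr(res, "condition"))
    } else {
      entries[[length(entries) + 1L]] <- res
    }
  }
  if (length(entries) == 0L) stop("every manifest entry failed")
  tab <- delta_table(entries)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(tab), file.path(out_dir, "panel.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(provenance = .provenance(
             unlist(lapply(manifest, function(e) c(e$apo, e$holo))),
             manifest_path),
           n_rows = nrow(tab), failures = failures),
      file.path(out_dir, "panel_summary.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(table = tab, failures = failures)
}

#' Ensemble plasticity analysis
#'
#' Pairwise main-chain+CB RMSD, GROMOS clustering at the configured
#' cutoff, the catalytic-Ser sidechain SASA series, and a two-Gaussian
#' mixture fit of that series. Writes `clusters.json`, `sasa.csv` and
#' `mixture.json` when `out_dir` is given.
#'
#' @param ensemble Ensemble, or path(s) for [read_ensemble()]
#' @param site SiteDefinition or config path
#' @param out_dir output directory or NULL
#' @param cparams [clustering_params()]
#' @param sparams [sasa_params()]
#' @return list with `clusters`, `sasa` (numeric series), `fit`
#'   (GaussianMixtureFit or NULL when the series is near-constant)
#' @export
run_ensemble <- function(ensemble, site, out_dir = NULL,
                         cparams = clustering_params(),
                         sparams = sasa_params()) {
  paths <- NULL
  if (is.character(ensemble)) { paths <- ensemble; ensemble <- read_ensemble(ensemble) }
  if (is.character(site)) site <- read_site_config(site)
  if (length(ensemble$frames) < 2L) stop("at least 2 frames required")
  m <- pairwise_rmsd_matrix(ensemble, cparams)
  clusters <- gromos_cluster(m, cparams$cutoff)
  sasa <- sasa_series(ensemble, site, params = sparams)
  fit <- NULL
  fit_error <- NULL
  fit <- tryCatch(fit_two_gaussians(sasa),
                  error = function(e) { fit_error <<- conditionMessage(e); NULL })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- .provenance(if (is.null(paths)) character(0) else paths)
    jsonlite::write_json(
      list(provenance = prov, cutoff = cparams$cutoff,
           selection = cparams$atoms,
           assignment = clusters$assignment,
           representative = clusters$representative,
           size = clusters$size, fraction = clusters$fraction),
      file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(
      data.frame(frame = seq_along(sasa), label = ensemble$labels,
                 ser_sidechain_sasa = sasa),
      file.path(out_dir, "sasa.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(list(provenance = prov,
             probe_radius = sparams$probe_radius,
             n_points = sparams$n_points),
        if (is.null(fit)) list(error = fit_error) else
          list(mean = fit$mean, sigma = fit$sigma, weight = fit$weight,
               loglik = fit$loglik, degenerate = fit$degenerate)),
      file.path(out_dir, "mixture.json"), auto_unbox = TRUE, digits = NA)
  }
  list(clusters = clusters, sasa = sasa, fit = fit, rmsd_matrix = m)
}

.cli_usage <- function() {
  paste(
    "usage: sitegeom <command> [options]",
    "",
    "commands:",
    "  compare  --apo FILE --holo FILE --site CONFIG --out DIR",
    "           [--pairing REF=MOB,...] [--cutoff 3.5]",
    "  panel    --manifest FILE [--out DIR]",
    "  ensemble --frames FILE[,FILE...] --site CONFIG --out DIR",
    "           [--cutoff 1.0] [--probe-radius 1.4] [--n-points 960]",
    "  sasa     --model FILE --site CONFIG --out DIR",
    "           [--probe-radius 1.4] [--n-points 960]",
    "  fixtures --out DIR [--seed 1] [--loop-shift 0.75] [--noise 0]",
    "  fetch    --id PDBID --out DIR   (network required)",
    sep = "\n")
}

.cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the subcommands documented by the usage string (run with no
#' arguments to print it). Designed to back a thin
#' `Rscript -e 'sitegeom::sitegeom_cli()'` wrapper or the installed
#' `exec/sitegeom` script.
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`)
#' @return exit status, invisibly (0 on success)
#' @export
sitegeom_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) { cat(.cli_usage(), "\n"); return(invisible(1L)) }
  cmd <- args[1L]
  opts <- .cli_opts(args[-1L])
  need <- function(key) {
    if (is.null(opts[[key]])) stop("missing required option --", key)
    opts[[key]]
  }
  status <- tryCatch({
    switch(
      cmd,
      compare = {
        pairing <- "by_id"
        if (!is.null(opts$pairing)) {
          kv <- strsplit(strsplit(opts$pairing, ",")[[1L]], "=")
          pairing <- setNames(vapply(kv, `[`, "", 2L),
                              vapply(kv, `[`, "", 1L))
        }
        run_compare(need("apo"), need("holo"), need("site"), need("out"),
                    chain_pairing = pairing,
                    hbond_cutoff = as.numeric(opts$cutoff %||% 3.5))
        0L
      },
      panel = {
        run_panel(need("manifest"), out_dir = opts$out)
        0L
      },
      ensemble = {
        run_ensemble(strsplit(need("frames"), ",")[[1L]], need("site"),
                     need("out"),
                     cparams = clustering_params(
                       cutoff = as.numeric(opts$cutoff %||% 1.0)),
                     sparams = sasa_params(
                       probe_radius = as.numeric(opts[["probe-radius"]] %||% 1.4),
                       n_points = as.integer(opts[["n-points"]] %||% 960L)))
        0L
      },
      sasa = {
        model <- parse_structure(need("model"))
        site <- read_site_config(need("site"))
        params <- sasa_params(
          probe_radius = as.numeric(opts[["probe-radius"]] %||% 1.4),
          n_points = as.integer(opts[["n-points"]] %||% 960L))
        res <- shrake_rupley(model, params)
        dir.create(need("out"), recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(res$per_atom,
                         file.path(opts$out, "sasa_atoms.csv"),
                         row.names = FALSE)
        ser <- vapply(site_chains(model, site), function(ch) {
          ser_sidechain_sasa(model, site, params, chain = ch)
        }, numeric(1))
        jsonlite::write_json(
          list(provenance = .provenance(need("model")),
               probe_radius = params$probe_radius,
               n_points = params$n_points,
               total = res$total, ser_sidechain = as.list(ser)),
          file.path(opts$out, "sasa_summary.json"), auto_unbox = TRUE,
          digits = NA)
        0L
      },
      fixtures = {
        dir.create(need("out"), recursive = TRUE, showWarnings = FALSE)
        seed <- as.integer(opts$seed %||% 1L)
        fix <- make_toy_hydrolase(seed = seed,
                                  noise_sigma = as.numeric(opts$noise %||% 0))
        write_fixture(fix$model, file.path(opts$out, "apo.pdb"))
        holo <- make_holo_from_apo(
          fix, loop_shift = as.numeric(opts[["loop-shift"]] %||% 0.75),
          seed = seed)
        write_fixture(holo, file.path(opts$out, "holo.pdb"))
        write_site_config(fix$site, file.path(opts$out, "site.json"),
                          provenance = "generated toy fixture")
        0L
      },
      fetch = {
        id <- toupper(need("id"))
        dir.create(need("out"), recursive = TRUE, showWarnings = FALSE)
        dest <- file.path(opts$out, paste0(tolower(id), ".pdb"))
        url <- sprintf("https://files.rcsb.org/download/%s.pdb", id)
        utils::download.file(url, dest, quiet = TRUE)
        0L
      },
      { cat(.cli_usage(), "\n"); 1L }
    )
  }, error = function(e) {
    message("sitegeom ", cmd, ": ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
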