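test_that("site configs round-trip through JSON and the shipped configs load", {
  fix <- make_toy_hydrolase(seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_site_config(fix$site, path, provenance = "toy")
  site <- read_site_config(path)
  expect_equal(site$name, fix$site$name)
  expect_equal(site$ser$resseq, fix$site$ser$resseq)
  expect_equal(site$oxyanion_donors[[1]]$atom, "N")
  expect_equal(site$core[[1]]$start, fix$site$core[[1]]$start)
  expect_equal(site$ligand$atoms, fix$site$ligand$atoms)
  expect_equal(attr(site, "provenance"), "toy")

  papeh <- read_site_config(shipped_site_config("papeh"))
  expect_equal(papeh$ser$resseq, 587L)
  expect_equal(papeh$his$resseq, 707L)
  expect_equal(papeh$asp$resseq, 675L)
  donor <- papeh$oxyanion_donors[[papeh$distal_donor_index]]
  expect_equal(donor$ref$resseq, 509L)
  expect_equal(donor$atom, "N")
  expect_equal(papeh$oxyanion_loop$start, 508L)
  expect_equal(papeh$oxyanion_loop$end, 511L)

  dpp4 <- read_site_config(shipped_site_config("dpp4"))
  dd <- dpp4$oxyanion_donors[[dpp4$distal_donor_index]]
  expect_equal(dd$ref$resseq, 547L)
  expect_equal(dd$atom, "OH")  # Tyr hydroxyl oxygen, not a backbone N
  expect_error(shipped_site_config("nope"), "no shipped")
  expect_error(read_site_config(withr::local_tempfile()), "cannot read")
})

test_that("the compare pipeline reproduces planted shifts from files", {
  dir <- withr::local_tempdir()
  fix <- make_toy_hydrolase(seed = 7)
  holo <- make_holo_from_apo(fix, loop_shift = 0.75, seed = 17)
  apo_path <- file.path(dir, "apo.pdb"); holo_path <- file.path(dir, "holo.pdb")
  write_pdb(fix$model, apo_path); write_pdb(holo, holo_path)
  cfg <- file.path(dir, "site.json")
  write_site_config(fix$site, cfg)
  out <- file.path(dir, "out")
  res <- run_compare(apo_path, holo_path, cfg, out)
  i <- which(res$shift$summary$resseq == 4 & res$shift$summary$atom == "N")
  # PDB coordinate quantization (0.001 A) bounds the round-trip error
  expect_equal(res$shift$summary$mean[i], 0.75, tolerance = 1e-2)
  expect_equal(res$shift$summary$display[i],
               round(res$shift$summary$mean[i], 1))
  expect_true(file.exists(file.path(out, "shift.json")))
  expect_true(file.exists(file.path(out, "shift.csv")))
  expect_true(file.exists(file.path(out, "delta.csv")))
  js <- jsonlite::read_json(file.path(out, "shift.json"))
  expect_equal(js$provenance$tool, "sitegeom")
  expect_true(nzchar(js$provenance$version))
  expect_length(js$provenance$input_md5, 2L)
  # ligand contacts are classified
  expect_false(is.null(res$contacts))
  expect_true(all(res$contacts$hbond %in% c("bond", "too_far")))

  # apo against itself: all-zero report
  res0 <- run_compare(apo_path, apo_path, cfg, NULL)
  expect_lt(max(res0$shift$per_atom$displacement), 1e-9)
  expect_equal(unname(unlist(res0$delta[, c("dd1", "dd2", "dd3")])),
               c(0, 0, 0))
})

test_that("the panel isolates failures and checks label uniqueness", {
  dir <- withr::local_tempdir()
  paths <- list()
  for (s in 1:2) {
    fix <- make_toy_hydrolase(seed = s)
    holo <- make_holo_from_apo(fix, loop_shift = 0.3 * s, seed = s + 20)
    ap <- file.path(dir, sprintf("apo%d.pdb", s))
    hp <- file.path(dir, sprintf("holo%d.pdb", s))
    write_pdb(fix$model, ap); write_pdb(holo, hp)
    cfg <- file.path(dir, sprintf("site%d.json", s))
    write_site_config(fix$site, cfg)
    paths[[s]] <- list(label = sprintf("pair%d", s), apo = ap, holo = hp,
                       site = cfg)
  }
  bad <- list(label = "broken", apo = file.path(dir, "nope.pdb"),
              holo = paths[[1]]$holo, site = paths[[1]]$site)
  out <- file.path(dir, "panel")
  res <- run_panel(c(paths, list(bad)), out_dir = out)
  expect_equal(nrow(res$table), 2L)
  expect_named(res$failures, "broken")
  expect_true(file.exists(file.path(out, "panel.csv")))
  summary <- jsonlite::read_json(file.path(out, "panel_summary.json"))
  expect_named(summary$failures, "broken")
  dup <- c(paths, list(paths[[1]]))
  expect_error(run_panel(dup), "duplicate")
  expect_error(run_panel(list()), "empty")
})

test_that("the ensemble pipeline ties clustering, SASA and the fit together", {
  gen <- make_ensemble(seed = 31, n_frames = 56)  # >= 50 for the fit
  dir <- withr::local_tempdir()
  res <- run_ensemble(gen$ensemble, gen$site, out_dir = dir)
  expect_length(res$clusters$size, 2L)
  expect_false(is.null(res$fit))
  expect_lt(abs(res$fit$mean[1] - 9.0), 1.0)
  expect_lt(abs(res$fit$mean[2] - 29.5), 1.0)
  for (f in c("clusters.json", "sasa.csv", "mixture.json")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  mix <- jsonlite::read_json(file.path(dir, "mixture.json"))
  expect_equal(mix$n_points, 960L)
  expect_equal(mix$probe_radius, 1.4)

  # constant ensemble: one cluster, mixture fit refuses and says why
  fix <- make_toy_hydrolase(seed = 1, n_chains = 1)
  const <- as_ensemble(rep(list(fix$model), 3))
  res0 <- run_ensemble(const, fix$site)
  expect_length(res0$clusters$size, 1L)
  expect_null(res0$fit)
  expect_error(run_ensemble(as_ensemble(list(fix$model)), fix$site),
               "at least 2")
})

test_that("the command-line interface drives fixtures and compare end to end", {
  dir <- withr::local_tempdir()
  fdir <- file.path(dir, "fx")
  status <- sitegeom_cli(c("fixtures", "--out", fdir, "--seed", "4",
                           "--loop-shift", "0.75"))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(fdir, "apo.pdb")))
  expect_true(file.exists(file.path(fdir, "holo.pdb")))
  expect_true(file.exists(file.path(fdir, "site.json")))
  out <- file.path(dir, "cmp")
  status <- sitegeom_cli(c("compare", "--apo", file.path(fdir, "apo.pdb"),
                           "--holo", file.path(fdir, "holo.pdb"),
                           "--site", file.path(fdir, "site.json"),
                           "--out", out))
  expect_equal(status, 0L)
  shift <- jsonlite::read_json(file.path(out, "shift.json"),
                               simplifyVector = TRUE)
  i <- which(shift$summary$resseq == 4 & shift$summary$atom == "N")
  expect_equal(shift$summary$mean[i], 0.75, tolerance = 1e-2)
  # structured failure: missing option and unknown command
  expect_equal(suppressMessages(sitegeom_cli(c("compare", "--apo", "x.pdb"))),
               1L)
  out <- capture.output(status <- sitegeom_cli("frobnicate"))
  expect_equal(status, 1L)
  expect_match(out[1], "usage")
})
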