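test_that("atom distances are Euclidean, symmetric and zero on self", {
  m <- tiny_model(rbind(c(0, 0, 0), c(3, 4, 0)), atoms = c("CA", "CA"),
                  resseq = c(1, 2))
  a <- list(ref = residue_ref(1), atom = "CA")
  b <- list(ref = residue_ref(2), atom = "CA")
  expect_equal(atom_distance(m, a, a, chain = "A"), 0)
  expect_equal(atom_distance(m, a, b, chain = "A"), 5.0)
  expect_equal(atom_distance(m, b, a, chain = "A"), 5.0)
  expect_error(atom_distance(m, a, list(ref = residue_ref(9), atom = "CA"),
                             chain = "A"), "missing")
})

test_that("a unit equilateral site yields d1 = d2 = d3 = 1", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                  c(10, 10, 10))
  m <- tiny_model(coords, atoms = c("CA", "CA", "N", "CA"),
                  resseq = c(1, 2, 3, 4),
                  resname = c("SER", "HIS", "GLY", "ASP"))
  site <- site_definition(
    "equilateral", ser = residue_ref(1), his = residue_ref(2),
    asp = residue_ref(4),
    oxyanion_donors = list(list(ref = residue_ref(3), atom = "N")))
  tri <- triad_triangle(m, site)
  expect_equal(unname(tri$mean), c(1, 1, 1))
})

test_that("triangle values equal direct coordinate arithmetic on the fixture", {
  fix <- make_toy_hydrolase(seed = 4, noise_sigma = 0.05)
  tri <- triad_triangle(fix$model, fix$site)
  for (i in seq_len(nrow(tri$per_chain))) {
    ch <- tri$per_chain$chain[i]
    oracle <- triangle_oracle(fix$model, ch, ser = 7, his = 11,
                              donor_res = 4, donor_atom = "N")
    expect_equal(as.numeric(tri$per_chain[i, c("d1", "d2", "d3")]),
                 unname(oracle), tolerance = 1e-12)
  }
  # invariants: triangle inequality and mean inside the per-chain range
  pc <- tri$per_chain
  for (i in seq_len(nrow(pc))) {
    d <- as.numeric(pc[i, c("d1", "d2", "d3")])
    expect_true(all(d <= sum(d) - d + 1e-12))
  }
  for (col in c("d1", "d2", "d3")) {
    expect_gte(tri$mean[[col]], min(pc[[col]]))
    expect_lte(tri$mean[[col]], max(pc[[col]]))
  }
})

test_that("per-chain spread vanishes on the symmetric fixture and stays below the noise", {
  tri0 <- triad_triangle(make_toy_hydrolase(seed = 1)$model,
                         make_toy_hydrolase(seed = 1)$site)
  expect_true(all(tri0$sd < 1e-12))
  noisy <- make_toy_hydrolase(seed = 6, noise_sigma = 0.05)
  trin <- triad_triangle(noisy$model, noisy$site)
  expect_true(all(trin$sd <= 0.05 * 4))  # a few sigma of planted noise
})

test_that("hydrogen-bond classification uses an inclusive 3.5 A default cutoff", {
  expect_equal(hbond_classify(c(3.9, 3.6)), c("too_far", "too_far"))
  expect_equal(hbond_classify(2.8), "bond")
  expect_equal(hbond_classify(3.5), "bond")  # documented inclusive boundary
  expect_equal(hbond_classify(3.6, cutoff = 3.7), "bond")
  expect_error(hbond_classify(-0.1), "negative")
})

test_that("an apo model compared with itself shows zero shift everywhere", {
  fix <- make_toy_hydrolase(seed = 1)
  rep <- loop_shift(fix$model, fix$model, fix$site,
                    list(list(ref = residue_ref(4), atom = "N"),
                         list(ref = residue_ref(11), atom = "CA")))
  expect_true(all(rep$per_atom$displacement < 1e-9))
  expect_true(all(rep$summary$direction == "n/a"))
})

test_that("a planted 0.75 A loop shift is recovered with the right direction", {
  fix <- make_toy_hydrolase(seed = 2)
  holo <- make_holo_from_apo(fix, loop_shift = 0.75, seed = 5)
  rep <- loop_shift(fix$model, holo, fix$site,
                    list(list(ref = residue_ref(4), atom = "N"),
                         list(ref = residue_ref(4), atom = "CA")))
  expect_equal(rep$summary$mean, rep(0.75, 2), tolerance = 1e-6)
  expect_true(all(rep$per_atom$direction == "toward"))
  # chain average lies inside the per-chain range
  for (k in unique(paste(rep$per_atom$resseq, rep$per_atom$atom))) {
    sub <- rep$per_atom[paste(rep$per_atom$resseq, rep$per_atom$atom) == k, ]
    i <- which(paste(rep$summary$resseq, rep$summary$atom) == k)
    expect_gte(rep$summary$mean[i], min(sub$displacement) - 1e-12)
    expect_lte(rep$summary$mean[i], max(sub$displacement) + 1e-12)
  }
})

test_that("loop shift is invariant to an extra rigid motion of the holo input", {
  fix <- make_toy_hydrolase(seed = 3)
  holo <- make_holo_from_apo(fix, loop_shift = 0.6, seed = 9)
  atoms <- list(list(ref = residue_ref(4), atom = "N"))
  r1 <- loop_shift(fix$model, holo, fix$site, atoms)
  moved <- transform_model(holo, rigid_transform(random_rotation(31),
                                                 c(12, -4, 9)))
  r2 <- loop_shift(fix$model, moved, fix$site, atoms)
  expect_equal(r1$per_atom$displacement, r2$per_atom$displacement,
               tolerance = 1e-6)
  expect_identical(r1$per_atom$direction, r2$per_atom$direction)
})

test_that("delta tables carry exact holo minus apo differences with fixed columns", {
  fix <- make_toy_hydrolase(seed = 1)
  tri <- triad_triangle(fix$model, fix$site)
  same <- delta_table(list(list(label = "self", apo = tri, holo = tri)))
  expect_equal(unname(unlist(same[, c("dd1", "dd2", "dd3")])), c(0, 0, 0))
  # planted differences propagate exactly
  tri2 <- tri
  tri2$mean <- tri$mean + c(d1 = 0.5, d2 = -0.3, d3 = 0.1)
  tab <- delta_table(list(list(label = "a", apo = tri, holo = tri2),
                          list(label = "b", apo = tri2, holo = tri)))
  expect_identical(names(tab),
                   c("label", "d1_apo", "d2_apo", "d3_apo", "d1_holo",
                     "d2_holo", "d3_holo", "dd1", "dd2", "dd3"))
  expect_equal(unname(unlist(tab[1, c("dd1", "dd2", "dd3")])),
               c(0.5, -0.3, 0.1))
  expect_equal(unname(unlist(tab[2, c("dd1", "dd2", "dd3")])),
               c(-0.5, 0.3, -0.1))
  expect_error(delta_table(list()), "empty")
})

test_that("site definitions reject inconsistent machinery", {
  expect_error(site_definition(
    "bad", ser = residue_ref(1), his = residue_ref(1), asp = residue_ref(3),
    oxyanion_donors = list(list(ref = residue_ref(5), atom = "N"))),
    "distinct")
  expect_error(site_definition(
    "bad", ser = residue_ref(1), his = residue_ref(2), asp = residue_ref(3),
    oxyanion_donors = list(list(ref = residue_ref(5), atom = "N")),
    distal_donor_index = 2), "out of range")
  expect_error(site_definition(
    "bad", ser = residue_ref(1), his = residue_ref(2), asp = residue_ref(3),
    oxyanion_donors = list(list(ref = residue_ref(5), atom = "N")),
    oxyanion_loop = list(chain = NA, start = 4, end = 8),
    his_loop = list(chain = NA, start = 7, end = 9)), "overlap")
})

test_that("a sidechain-oxygen donor is honored for DPP4-style sites", {
  # donor heteroatom = Tyr-like sidechain OH instead of a backbone N
  coords <- rbind(c(0, 0, 0), c(4, 0, 0), c(1, 3, 0), c(9, 9, 9))
  m <- tiny_model(coords, atoms = c("CA", "CA", "OH", "CA"),
                  resseq = c(1, 2, 3, 4),
                  resname = c("SER", "HIS", "TYR", "ASP"))
  site <- site_definition(
    "tyr-donor", ser = residue_ref(1), his = residue_ref(2),
    asp = residue_ref(4),
    oxyanion_donors = list(list(ref = residue_ref(3), atom = "OH")))
  tri <- triad_triangle(m, site)
  expect_equal(tri$mean[["d2"]], sqrt(10))
  expect_equal(tri$mean[["d3"]], sqrt(18))
})
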