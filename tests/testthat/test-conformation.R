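# Crossover-helix detection, diagnostic distances, Closed/Open classification.

test_that("curated helix spans pass through; geometry detection finds ideal helices", {
  refs <- test_registry()
  res <- make_complex(complex_spec("closed", seed = 2), write = FALSE)
  h <- find_crossover_helix(res$complex, "B", curated = c(98, 113))
  expect_equal(list(h$start, h$end, h$source), list(98L, 113L, "curated"))

  # ideal poly-Ala helix placed after the cysteine at residue 10
  pre <- cbind(1.5 * (1:10) - 40, 6 * ((1:10) %% 3), 2 * ((1:10) %% 2))
  hx <- ideal_helix(20, origin = c(0, 0, 0))
  cx <- micro_complex(rbind(ca_chain("B", pre, resname = c(rep("ALA", 9), "CYS")),
                            ca_chain("B", hx, start_resno = 11L)))
  det <- find_crossover_helix(cx, "B", cys_resno = 10)
  expect_lte(abs(det$start - 11L), 1)
  expect_equal(det$source, "detected")

  # fully extended chain has no helical geometry
  ext <- micro_complex(ca_chain("B", cbind(3.5 * (1:30), 0, 0),
                                resname = c(rep("ALA", 4), "CYS", rep("ALA", 25))))
  expect_error(find_crossover_helix(ext, "B", cys_resno = 5), "no crossover helix")
})

test_that("diagnostic distances equal constructed values", {
  # Ile44 CA coincident with a helix CA -> 0; at (0,0,7) from nearest -> 7
  hx <- ideal_helix(10, origin = c(0, 0, 0))
  e2 <- ca_chain("B", hx, start_resno = 39L)
  ub0 <- atomdf("A", 44L, "ILE", "CA", hx[1, 1], hx[1, 2], hx[1, 3])
  cx0 <- micro_complex(rbind(e2, ub0))
  copy <- list(ub = "A", e2 = "B", e3 = NA)
  helix <- list(chain = "B", start = 39L, end = 48L, source = "curated")
  expect_equal(ile44_helix_distance(cx0, copy, helix), 0.0)

  far <- rbind(e2, atomdf("A", 44L, "ILE", "CA",
                          hx[1, 1], hx[1, 2], hx[1, 3] - 7))
  expect_equal(ile44_helix_distance(micro_complex(far), copy, helix), 7.0,
               tolerance = 1e-9)

  # tail distance: constructed 11.9 A; coincident -> 0
  at <- rbind(atomdf("B", 25L, "CYS", "CA", 0, 0, 0),
              atomdf("A", 76L, "GLY", "C", 0, 0, 11.9))
  expect_equal(tail_cys_distance(micro_complex(at), copy, 25L)$dist, 11.9)
  at2 <- rbind(atomdf("B", 25L, "CYS", "CA", 1, 2, 3),
               atomdf("A", 76L, "GLY", "C", 1, 2, 3))
  expect_equal(tail_cys_distance(micro_complex(at2), copy, 25L)$dist, 0.0)
  # unresolved residue 76 -> fallback to the last resolved tail residue, flagged
  at3 <- rbind(atomdf("B", 25L, "CYS", "CA", 0, 0, 0),
               atomdf("A", 74L, "ARG", "C", 0, 0, 5))
  tc <- tail_cys_distance(micro_complex(at3), copy, 25L)
  expect_equal(tc$dist, 5.0)
  expect_true(tc$flagged)
  # no catalytic cysteine -> absent value, not an error
  expect_true(is.na(tail_cys_distance(micro_complex(at3), copy, NA)$dist))
})

test_that("classification applies the cutoffs with strict inequality", {
  entry <- list(helix_start = 39L, helix_end = 54L, catalytic_cys = 25L)
  call_for <- function(conf, d44, dtail, mode = "predicted") {
    cx <- assigned_synthetic(complex_spec(conf, d44, dtail, seed = 21))
    classify_conformation(cx, registry_entry = entry,
                          params = cutoff_params(apply_tail_criterion = mode == "predicted"))
  }
  expect_equal(call_for("closed", 6.9, 4.2)$label, "Closed")
  expect_equal(call_for("open", 9.5, 13.0)$label, "Open")    # tail criterion fails
  expect_equal(call_for("open", 9.5, 13.0, mode = "experimental")$label, "Closed")
  expect_equal(call_for("open", 15, 20)$label, "Open")
  # boundary-equal distances are Open (strict inequality); exact construction
  # curated spans need no helical geometry: integer coordinates keep the
  # boundary distances exactly representable
  hx <- cbind(4 * (0:15), 0, 0)
  bnd <- micro_complex(rbind(
    ca_chain("B", hx, start_resno = 39L),
    atomdf("B", 25L, "CYS", "CA", 30, -10, 0),
    atomdf("A", 44L, "ILE", "CA", 0, 10, 0),
    atomdf("A", 76L, "GLY", "C", 42, -10, 0)))
  bnd$roles <- c(A = "UBIQUITIN", B = "E2")
  bnd$copies <- list(list(ub = "A", e2 = "B", e3 = NA))
  for (mode in c(TRUE, FALSE)) {
    cl <- classify_conformation(bnd, registry_entry = entry,
                                params = cutoff_params(apply_tail_criterion = mode))
    expect_equal(cl$ile44_helix_dist, 10.0, tolerance = 1e-9)
    expect_equal(cl$label, "Open")
  }
  # E2 without catalytic cysteine (UBE2V type): Open in predicted mode
  cx <- assigned_synthetic(complex_spec("closed", 6.9, 4.2, seed = 22))
  nocys <- classify_conformation(cx, registry_entry = list(helix_start = 39L,
                                                           helix_end = 54L,
                                                           catalytic_cys = NA))
  expect_equal(nocys$label, "Open")
  expect_true(is.na(nocys$tail_cys_dist))
})

test_that("distances are invariant under rigid transforms (1e-6 A)", {
  entry <- list(helix_start = 39L, helix_end = 54L, catalytic_cys = 25L)
  cx <- assigned_synthetic(complex_spec("closed", seed = 31))
  base <- classify_conformation(cx, registry_entry = entry)
  set.seed(17)
  for (i in 1:20) {
    tr <- transform_complex(cx, random_rot(), rnorm(3, 0, 30))
    cl <- classify_conformation(tr, registry_entry = entry)
    expect_equal(cl$ile44_helix_dist, base$ile44_helix_dist, tolerance = 1e-6)
    expect_equal(cl$tail_cys_dist, base$tail_cys_dist, tolerance = 1e-6)
    expect_equal(cl$label, base$label)
  }
})

test_that("translating ubiquitin away never converts Open to Closed", {
  entry <- list(helix_start = 39L, helix_end = 54L, catalytic_cys = 25L)
  cx <- assigned_synthetic(complex_spec("closed", 9.0, 4.0, seed = 41))
  helix <- list(chain = "B", start = 39L, end = 54L, source = "curated")
  copy <- cx$copies[[1]]
  p44 <- ubiqpair:::atom_coords(cx, copy$ub, "CA", 44L)$xyz[1, ]
  hres <- ubiqpair:::atom_coords(cx, copy$e2, "CA", 39:54)
  nearest <- hres$xyz[which.min(ubiqpair:::cross_dist(matrix(p44, 1), hres$xyz)), ]
  axis <- (p44 - nearest) / sqrt(sum((p44 - nearest)^2))
  prev_d <- -Inf; seen_open <- FALSE
  for (shift in c(0, 2, 5, 10, 20)) {
    cxs <- cx
    sel <- cxs$atoms$chain == copy$ub
    cxs$atoms$x[sel] <- cxs$atoms$x[sel] + shift * axis[1]
    cxs$atoms$y[sel] <- cxs$atoms$y[sel] + shift * axis[2]
    cxs$atoms$z[sel] <- cxs$atoms$z[sel] + shift * axis[3]
    cl <- classify_conformation(cxs, registry_entry = entry)
    expect_gte(cl$ile44_helix_dist + 1e-9, prev_d)
    prev_d <- cl$ile44_helix_dist
    if (cl$label == "Open") seen_open <- TRUE
    if (seen_open) expect_equal(cl$label, "Open")
  }
  expect_true(seen_open)
})

test_that("copy averaging: two identical copies equal the single-copy call", {
  entry <- list(helix_start = 39L, helix_end = 54L, catalytic_cys = 25L)
  one <- assigned_synthetic(complex_spec("closed", seed = 51))
  two <- assigned_synthetic(complex_spec("closed", n_copies = 2, seed = 51))
  c1 <- classify_conformation(one, registry_entry = entry)
  c2 <- classify_conformation(two, registry_entry = entry)
  expect_equal(c2$n_copies_averaged, 2L)
  expect_equal(c2$ile44_helix_dist, c1$ile44_helix_dist, tolerance = 1e-6)
  expect_equal(c2$tail_cys_dist, c1$tail_cys_dist, tolerance = 1e-6)
  expect_equal(c2$label, c1$label)
})

test_that("a closed ensemble built at the observed medians classifies Closed", {
  # pair-set medians: 6.86 A (Ile44-helix), 4.18 A (tail-cysteine)
  entry <- list(helix_start = 39L, helix_end = 54L, catalytic_cys = 25L)
  set.seed(61)
  d44 <- pmin(9.5, pmax(4, rnorm(15, 6.86, 0.8)))
  dtl <- pmin(11, pmax(2, rnorm(15, 4.18, 0.6)))
  calls <- vapply(1:15, function(i) {
    cx <- assigned_synthetic(complex_spec("closed", d44[i], dtl[i], seed = 100 + i))
    cl <- classify_conformation(cx, registry_entry = entry)
    c(cl$ile44_helix_dist, cl$tail_cys_dist)
  }, numeric(2))
  expect_lt(median(calls[1, ]), 10)
  expect_lt(median(calls[2, ]), 12)
})
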