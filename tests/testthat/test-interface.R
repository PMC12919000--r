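# Interface residues, hydrogen bonds, loop engagement, linchpin, interface RMSD.

test_that("interface residues match construction and the brute-force oracle", {
  copy <- list(ub = "A", e2 = "B", e3 = NA)
  # chains 50 A apart -> empty
  cx <- micro_complex(rbind(ca_chain("A", cbind(1:3 * 3.8, 0, 0)),
                            ca_chain("B", cbind(1:3 * 3.8, 50, 0))))
  expect_equal(nrow(interface_residues(cx, copy, "UB-E2")), 0L)
  # single CA pair at 7.9 A -> exactly those two residues
  cx2 <- micro_complex(rbind(ca_chain("A", rbind(c(0, 0, 0), c(-20, 0, 0), c(-40, 0, 0))),
                             ca_chain("B", rbind(c(7.9, 0, 0), c(30, 0, 0), c(50, 0, 0)))))
  ir <- interface_residues(cx2, copy, "UB-E2")
  expect_equal(ir$resno[ir$chain == "A"], 1L)
  expect_equal(ir$resno[ir$chain == "B"], 1L)
  expect_error(interface_residues(cx2, copy, "UB-XX"), "unknown interface")
  # dense random fixture vs O(n^2) oracle
  set.seed(71)
  for (k in 1:10) {
    xa <- matrix(rnorm(20 * 3, 0, 6), 20)
    xb <- matrix(rnorm(15 * 3, 2, 6), 15)
    cxk <- micro_complex(rbind(ca_chain("A", xa), ca_chain("B", xb)))
    got <- interface_residues(cxk, copy, "UB-E2")
    want <- oracle_interface(xa, xb, 1:20, 1:15)
    expect_equal(sort(got$resno[got$chain == "A"]), want$a)
    expect_equal(sort(got$resno[got$chain == "B"]), want$b)
  }
})

test_that("hydrogen-bond detection applies the 3.5 A donor-acceptor rule", {
  mk <- function(d) micro_complex(rbind(
    atomdf("A", 1, "ALA", "N", 0, 0, 0),
    atomdf("B", 1, "ALA", "O", d, 0, 0)))
  expect_equal(nrow(detect_hbonds(mk(3.4), "A", "B")), 1L)
  expect_equal(nrow(detect_hbonds(mk(3.6), "A", "B")), 0L)
  # carbon/sulfur atoms never count
  cxs <- micro_complex(rbind(atomdf("A", 1, "CYS", "SG", 0, 0, 0),
                             atomdf("A", 1, "CYS", "CA", 0, 1, 0),
                             atomdf("B", 1, "ALA", "O", 2, 0, 0)))
  expect_equal(nrow(detect_hbonds(cxs, "A", "B")), 0L)
  # five planted contacts, count equals exhaustive scan, symmetric in chain order
  set.seed(72)
  base <- matrix(rnorm(12 * 3, 0, 8), 12)
  ata <- data.frame(chain = "A", resno = 1:12, resname = "ALA",
                    atom = rep(c("N", "O", "CB"), 4),
                    x = base[, 1], y = base[, 2], z = base[, 3],
                    stringsAsFactors = FALSE)
  atb <- ata
  atb$chain <- "B"
  atb$x <- atb$x + 40
  # plant 5 contacts: move five B polar atoms within 3 A of A polar atoms
  pol_a <- which(ata$atom %in% c("N", "O"))[1:5]
  pol_b <- which(atb$atom %in% c("N", "O"))[1:5]
  atb$x[pol_b] <- ata$x[pol_a] + 3.0
  atb$y[pol_b] <- ata$y[pol_a]
  atb$z[pol_b] <- ata$z[pol_a]
  cx5 <- micro_complex(rbind(ata, atb))
  hb <- detect_hbonds(cx5, "A", "B")
  expect_equal(nrow(hb), oracle_hbonds(ata, atb))
  expect_equal(nrow(hb), nrow(detect_hbonds(cx5, "B", "A")))
  expect_gte(nrow(hb), 5L)
})

test_that("the E2 binding loop is the coil immediately N-terminal of the helix", {
  # strand 80-89, coil 90-97, helix 98-113
  strand <- cbind(3.5 * (1:10), 0, 0)
  coil <- rbind(c(38, 3, 2), c(40, 6, 0), c(42, 4, 3), c(44, 7, 1),
                c(46, 5, 4), c(48, 8, 2), c(50, 6, 5), c(52, 9, 3))
  hx <- ideal_helix(16, origin = c(56, 6, 4))
  cx <- micro_complex(rbind(ca_chain("B", strand, start_resno = 80L),
                            ca_chain("B", coil, start_resno = 90L),
                            ca_chain("B", hx, start_resno = 98L)))
  helix <- list(chain = "B", start = 98L, end = 113L, source = "curated")
  expect_equal(find_e2_binding_loop(cx, helix), c(90L, 97L))
  # a 20-residue upstream coil is capped at 12
  cx2 <- assigned_synthetic(complex_spec("closed", seed = 81))
  helix2 <- list(chain = "B", start = 39L, end = 54L, source = "curated")
  expect_equal(diff(find_e2_binding_loop(cx2, helix2)) + 1L, 12L)
  # curated override wins
  expect_equal(find_e2_binding_loop(cx, helix, curated = c(91, 95)), c(91L, 95L))
})

test_that("E3 loop engagement counts loops and residues in range", {
  copy <- list(ub = "A", e2 = "B", e3 = "C")
  e2_loop_xyz <- rbind(c(0, 0, 0), c(2, 2, 1), c(4, 0, 2), c(6, 2, 0))
  e2 <- ca_chain("B", e2_loop_xyz, start_resno = 30L)
  ub <- ca_chain("A", cbind(1:3 * 3.8, 60, 0))
  helixA <- ca_chain("C", ideal_helix(14, origin = c(-40, 0, 0)))
  loop1 <- ca_chain("C", rbind(c(0, 6, 1), c(2.5, 7.5, 0), c(5, 6, 2)),
                    start_resno = 15L)
  helixB <- ca_chain("C", ideal_helix(14, origin = c(-40, 20, 0)), start_resno = 18L)
  loop2 <- ca_chain("C", rbind(c(0, -6, 1), c(2, -7.5, 0), c(4, -6, 2), c(6, -7, 1)),
                    start_resno = 32L)
  helixC <- ca_chain("C", ideal_helix(14, origin = c(-40, -20, 0)), start_resno = 36L)
  cx <- micro_complex(rbind(ub, e2, helixA, loop1, helixB, loop2, helixC))
  eng <- e3_engagement(cx, copy, c(30L, 33L))
  expect_equal(eng$n_e3_loops, 2L)
  expect_equal(eng$n_e3_loop_residues, 7L)
  # translated 100 A away -> nothing engaged
  cx2 <- cx
  sel <- cx2$atoms$chain == "C"
  cx2$atoms$x[sel] <- cx2$atoms$x[sel] + 100
  eng2 <- e3_engagement(cx2, copy, c(30L, 33L))
  expect_equal(c(eng2$n_e3_loops, eng2$n_e3_loop_residues), c(0L, 0L))
  # counts are monotone non-increasing as the E3 moves away
  prev <- c(eng$n_e3_loops, eng$n_e3_loop_residues)
  for (shift in c(2, 4, 6, 8, 12)) {
    cxs <- cx
    cxs$atoms$y[sel] <- cxs$atoms$y[sel] + shift
    e <- e3_engagement(cxs, copy, c(30L, 33L))
    expect_lte(e$n_e3_loop_residues, prev[2])
    prev <- c(e$n_e3_loops, e$n_e3_loop_residues)
  }
})

test_that("linchpin calls follow the planted bridge geometry", {
  with_lp <- assigned_synthetic(complex_spec("closed", with_linchpin = TRUE, seed = 91))
  lp <- detect_linchpin(with_lp, helix_curated = c(39, 54), cys_resno = 25)
  expect_true(lp$present)
  expect_equal(lp$residue$resno, 18L)
  expect_equal(lp$residue$resname, "ARG")
  expect_equal(lp$fraction_of_copies, 1.0)
  # same construction with the guanidinium moved away -> absent
  no_lp <- assigned_synthetic(complex_spec("closed", with_linchpin = FALSE, seed = 91))
  lp2 <- detect_linchpin(no_lp, helix_curated = c(39, 54), cys_resno = 25)
  expect_false(lp2$present)
  expect_null(lp2$residue)
  # determinism
  lp3 <- detect_linchpin(with_lp, helix_curated = c(39, 54), cys_resno = 25)
  expect_identical(lp, lp3)
  # binary complex: undefined call
  bin <- with_lp
  bin$copies[[1]]$e3 <- NA
  expect_true(is.na(detect_linchpin(bin)$present))
})

test_that("half-of-copies rule: one positive of two copies is still present", {
  a <- make_complex(complex_spec("closed", with_linchpin = TRUE, seed = 93),
                    write = FALSE)$complex
  b <- make_complex(complex_spec("closed", with_linchpin = FALSE, seed = 93),
                    write = FALSE)$complex
  b$atoms$chain <- c(A = "D", B = "E", C = "F")[b$atoms$chain]
  b$atoms$x <- b$atoms$x + 400
  merged <- a
  merged$atoms <- rbind(a$atoms, b$atoms)
  refs <- test_registry()
  ov <- c(A = "UB", B = "E2", C = "E3", D = "UB", E = "E2", F = "E3")
  merged <- enumerate_copies(assign_roles(merged, refs, overrides = ov))
  lp <- detect_linchpin(merged, helix_curated = c(39, 54), cys_resno = 25)
  expect_equal(lp$fraction_of_copies, 0.5)
  expect_true(lp$present)
})

test_that("interface RMSD is zero under identity and rigid motion, analytic otherwise", {
  cx <- assigned_synthetic(complex_spec("closed", seed = 95))
  hx <- list(chain = "B", start = 39L, end = 54L, source = "curated")
  self <- interface_rmsd(cx, cx, ref_helix = hx, model_helix = hx)
  expect_equal(self$overall, 0, tolerance = 1e-9)
  set.seed(96)
  for (i in 1:5) {
    mod <- transform_complex(cx, random_rot(), rnorm(3, 0, 20))
    r <- interface_rmsd(cx, mod, ref_helix = hx, model_helix = hx)
    expect_equal(r$overall, 0, tolerance = 1e-6)
  }
  # displace the whole ubiquitin by a fixed vector: E2-anchored fit is
  # unaffected, so every UB interface residue deviates by exactly |v|
  v <- c(0.3, -0.4, 0.12); vlen <- sqrt(sum(v^2))
  mod <- cx
  sel <- mod$atoms$chain == "A"
  mod$atoms$x[sel] <- mod$atoms$x[sel] + v[1]
  mod$atoms$y[sel] <- mod$atoms$y[sel] + v[2]
  mod$atoms$z[sel] <- mod$atoms$z[sel] + v[3]
  r <- interface_rmsd(cx, mod, ref_helix = hx, model_helix = hx)
  ir_ref <- interface_residues(cx, cx$copies[[1]], "UB-E2")
  ir_mod <- interface_residues(mod, mod$copies[[1]], "UB-E2")
  common <- merge(ir_ref, ir_mod)
  n_ub <- sum(common$chain == "A"); n_tot <- nrow(common)
  expect_equal(unname(r$per_interface["UB-E2"]),
               sqrt(n_ub * vlen^2 / n_tot), tolerance = 1e-6)
  # too-short anchor
  expect_error(interface_rmsd(cx, cx,
                              ref_helix = list(chain = "B", start = 39L, end = 40L),
                              model_helix = list(chain = "B", start = 39L, end = 40L)),
               "insufficient anchor")
})
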