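# Deterministic synthetic-fixture generators: toy ternary-complex coordinates
# with tunable diagnostic distances and hydrogen-bond geometry, prediction-
# confidence JSON in both dialects, interaction edge tables, energetics
# tables, and labelled feature tables with planted pair/non-pair signal.
#
# The toy chains carry idealized backbones (N, CA, C, O; minimal side-chain
# atoms only where a measurement needs them) — enough for every quantity the
# pipeline measures, nothing more.

.UB_SEQ <- paste0(
  "MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYNIQKESTLHLVLRLRGG"
)
# synthetic E2: catalytic C at 25 (the only cysteine), crossover helix 39-54
.E2SYN_SEQ <- "MADLSKGEALRVAKELSDLERDPPCSAGASLEAVKDLMAAKEGLSDEQIKAAYRKLAMKN"
# synthetic E3: arginine at 18 inside the E2-binding loop; composition kept
# dissimilar from the E2 so registry matching cannot cross-assign the chains
.E3SYN_SEQ <- "MWTNYGQPFTHWDYSGTRYGHWNQTPGFYTHWDNSGQWGY"

#' Synthetic reference registry
#'
#' Registry rows for the synthetic ubiquitin / E2 / E3 chains emitted by
#' [make_complex()]: real human ubiquitin sequence; synthetic E2 with
#' catalytic cysteine 25 and curated crossover helix 39-54; synthetic E3.
#'
#' @param path optional TSV output path; when given, the registry is written
#'   and the path returned
#' @return data.frame (or `path`)
#' @export
synthetic_registry <- function(path = NULL) {
  df <- data.frame(
    gene = c("UBB", "E2SYN", "E3SYN"),
    uniprot = c("P0CG47", "SYN0001", "SYN0002"),
    type = c("UB", "E2", "E3"),
    sequence = c(.UB_SEQ, .E2SYN_SEQ, .E3SYN_SEQ),
    catalytic_cys = c(NA, 25L, NA),
    helix_start = c(NA, 39L, NA),
    helix_end = c(NA, 54L, NA),
    stringsAsFactors = FALSE
  )
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Specification for one synthetic ternary complex
#'
#' @param conformation `"closed"` or `"open"`; sets the default target
#'   distances (7.0 / 4.0 A closed, 15.0 / 20.0 A open)
#' @param ile44_target_dist Ile44-to-helix distance to build, A
#' @param tail_target_dist tail-to-cysteine distance to build, A
#' @param with_linchpin plant an arginine bridge satisfying the 3.5 A
#'   double-hydrogen-bond linchpin geometry
#' @param n_copies number of rigid-body replicas (separated by >= 100 A)
#' @param seed integer seed for path jitter
#' @return a `complex_spec` list
#' @export
complex_spec <- function(conformation = c("closed", "open"),
                         ile44_target_dist = NULL, tail_target_dist = NULL,
                         with_linchpin = conformation == "closed",
                         n_copies = 1L, seed = 1L) {
  conformation <- match.arg(conformation)
  if (is.null(ile44_target_dist)) {
    ile44_target_dist <- if (conformation == "closed") 7.0 else 15.0
  }
  if (is.null(tail_target_dist)) {
    tail_target_dist <- if (conformation == "closed") 4.0 else 20.0
  }
  if (ile44_target_dist <= 0 || tail_target_dist <= 0) {
    stop("construction error: target distances must be positive")
  }
  if (conformation == "closed" &&
      (ile44_target_dist >= .ILE44_CUTOFF || tail_target_dist >= .TAIL_CUTOFF)) {
    stop("construction error: closed spec requires targets below the cutoffs")
  }
  if (conformation == "open" &&
      ile44_target_dist < .ILE44_CUTOFF && tail_target_dist < .TAIL_CUTOFF) {
    stop("construction error: open spec requires a target at/above a cutoff")
  }
  list(conformation = conformation, ile44_target_dist = ile44_target_dist,
       tail_target_dist = tail_target_dist,
       with_linchpin = isTRUE(with_linchpin[1]),
       n_copies = as.integer(n_copies), seed = as.integer(seed))
}

.unit <- function(v) v / sqrt(sum(v^2))

# Ideal alpha-helix Calpha trace: radius 2.3 A, rise 1.5 A, 100 deg/residue.
.helix_ca <- function(n, origin = c(0, 0, 0), phase = 0) {
  i <- seq_len(n) - 1
  th <- (phase + 100 * i) * pi / 180
  cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i) +
    matrix(origin, n, 3, byrow = TRUE)
}

# Irregular coil trace: axial step 2.2 A plus period-3 perpendicular offsets,
# tuned so neither the helix nor the strand Calpha windows fire.
.zigzag <- function(start, dir, n, jitter = 0) {
  dir <- .unit(dir)
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p <- .unit(pracma_cross(dir, ref))
  q <- pracma_cross(dir, p)
  off <- c(0, 2.4, -2.4)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    out[i, ] <- start + (i - 1) * 2.2 * dir + off[(i - 1) %% 3 + 1] * p +
      0.8 * ((i - 1) %% 2) * q
  }
  if (jitter > 0) out <- out + matrix(rnorm(3 * n, 0, jitter), n, 3)
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Backbone atoms (N, CA, C, O) from a Calpha trace.
.backbone <- function(ca) {
  n <- nrow(ca)
  rows <- list()
  for (i in seq_len(n)) {
    prev <- if (i > 1) ca[i - 1, ] else ca[i, ] - (ca[min(i + 1, n), ] - ca[i, ])
    nxt <- if (i < n) ca[i + 1, ] else ca[i, ] + (ca[i, ] - ca[max(i - 1, 1), ])
    u <- nxt - prev
    if (sum(u^2) < 1e-8) u <- c(1, 0, 0)
    u <- .unit(u)
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    p <- .unit(pracma_cross(u, ref))
    q <- pracma_cross(u, p)
    rows[[i]] <- rbind(
      N = ca[i, ] - 1.2 * u + 0.4 * p,
      CA = ca[i, ],
      C = ca[i, ] + 1.2 * u + 0.4 * p,
      O = ca[i, ] + 1.2 * u + 0.4 * p + 1.23 * q
    )
  }
  rows
}

.atom_rows <- function(chain, resno, resname, atoms_xyz) {
  nm <- rownames(atoms_xyz)
  atoms_xyz <- unname(atoms_xyz)
  chain <- unname(chain); resno <- unname(resno)
  data.frame(chain = chain, resno = resno, ins = "", resname = resname,
             atom = nm, altloc = "",
             element = substr(gsub("[0-9]", "", nm), 1, 1),
             x = atoms_xyz[, 1], y = atoms_xyz[, 2], z = atoms_xyz[, 3],
             occ = 1, het = FALSE, stringsAsFactors = FALSE)
}

.res3 <- function(seq1, i) unname(.AA1TO3[substr(seq1, i, i)])

# Build one copy of the toy ternary complex in a local frame.
.build_copy <- function(spec, chains) {
  d44 <- spec$ile44_target_dist
  dtail <- spec$tail_target_dist
  rows <- list()
  add <- function(chain, resno, resname, xyz) {
    rows[[length(rows) + 1L]] <<- .atom_rows(chain, resno, resname, xyz)
  }

  ## --- E2 chain: stem (1-26, Cys25), binding loop (27-38), helix (39-54),
  ##     C-terminal coil (55-60)
  helix_ca <- .helix_ca(16)                       # residues 39-54, start (2.3,0,0)
  # walk away from the helix, then reorder so residue 38 sits next to it
  loop_ca <- .zigzag(helix_ca[1, ] + c(1.5, -3.2, -1.0),
                     c(0.25, -0.9, -0.35), 12)[12:1, , drop = FALSE]
  stem_ca <- .zigzag(loop_ca[1, ] + c(0.8, -2.0, 1.2),
                     c(0.55, -0.75, 0.35), 26)
  stem_ca <- stem_ca[nrow(stem_ca):1, , drop = FALSE]  # residue 1 farthest
  cterm_ca <- .zigzag(helix_ca[16, ] + c(0, 1.5, 3.0), c(-0.2, 0.4, 0.9), 6)
  e2_ca <- rbind(stem_ca, loop_ca, helix_ca, cterm_ca)
  e2_bb <- .backbone(e2_ca)
  for (i in 1:60) add(chains["e2"], i, .res3(.E2SYN_SEQ, i), e2_bb[[i]])
  p_cys <- e2_ca[25, ]
  add(chains["e2"], 25L, "CYS", rbind(SG = p_cys + c(0.9, -1.2, 0.6)))

  ## --- ubiquitin chain: residue 44 Calpha at d44 from the nearest helix
  ##     Calpha (radially out from the helix axis through residue 46)
  axis_pt <- c(0, 0, helix_ca[8, 3])
  radial <- .unit(helix_ca[8, 1:2])
  p44 <- helix_ca[8, ] + d44 * c(radial, 0)
  ub_body <- .zigzag(p44 + 2.2 * .unit(c(radial, 0) + c(0, 0, 1.2)),
                     .unit(c(radial, 0) + c(0, 0, 1.2)), 43)
  ub_body <- ub_body[nrow(ub_body):1, , drop = FALSE]   # residues 1-43
  t_hat <- .unit(c(-0.30, -0.70, -0.65))
  c76 <- p_cys + dtail * t_hat
  ca76 <- c76 + 1.5 * .unit(c(-0.8, -0.6, 0.4))
  ca71 <- ca76 + 5 * 2.2 * .unit(c(-0.15, 0.85, 0.50))
  tail_ca <- sapply(0:5, function(k) ca71 + (ca71 - ca76) / 5 * (-k))
  tail_ca <- t(tail_ca)                                  # residues 71-76
  mid_dir <- .unit(tail_ca[1, ] - p44)
  mid_ca <- matrix(0, 26, 3)                              # residues 45-70
  for (k in 1:26) {
    frac <- k / 27
    base <- p44 + frac * (tail_ca[1, ] - p44)
    perp <- .unit(pracma_cross(mid_dir, c(0, 0, 1)))
    mid_ca[k, ] <- base + 3.0 * sin(3 * frac * pi) * perp + c(0, 0, 2.5 * sin(frac * pi))
  }
  ub_ca <- rbind(ub_body, p44, mid_ca, tail_ca)
  ub_bb <- .backbone(ub_ca)
  for (i in 1:76) add(chains["ub"], i, .res3(.UB_SEQ, i), ub_bb[[i]])
  # exact placements for the measured atoms
  rows <- lapply(rows, function(df) {
    if (df$chain[1] == chains["ub"]) {
      df$x[df$resno == 44 & df$atom == "CA"] <- p44[1]
      df$y[df$resno == 44 & df$atom == "CA"] <- p44[2]
      df$z[df$resno == 44 & df$atom == "CA"] <- p44[3]
      df$x[df$resno == 76 & df$atom == "C"] <- c76[1]
      df$y[df$resno == 76 & df$atom == "C"] <- c76[2]
      df$z[df$resno == 76 & df$atom == "C"] <- c76[3]
    }
    df
  })

  ## --- E3 chain: two anchor helices far from the interface, an E2-binding
  ##     loop (15-22) near the E2 loop, optional arginine bridge at 18
  h1 <- .helix_ca(14, origin = c(-20, -12, -6))
  e3_loop <- .zigzag(c(12.0, -10.0, -6.5), c(0.05, 0.95, 0.45), 8)
  h2 <- .helix_ca(14, origin = c(-20, 6, 2), phase = 40)
  e3_tail <- .zigzag(h2[14, ] + c(-2, 2, 3), c(-0.5, 0.6, 0.6), 4)
  e3_ca <- rbind(h1, e3_loop, h2, e3_tail)
  e3_bb <- .backbone(e3_ca)
  for (i in 1:40) add(chains["e3"], i, .res3(.E3SYN_SEQ, i), e3_bb[[i]])

  ## linchpin geometry: Arg18 guanidinium nitrogens 3.0 A from (a) the
  ## ubiquitin residue-74 carbonyl O and (b) an E2 binding-loop carbonyl O
  o74 <- tail_ca[4, ] + c(0.6, -1.1, -0.9)            # ub residue 74 O
  rows <- lapply(rows, function(df) {
    if (df$chain[1] == chains["ub"]) {
      df$x[df$resno == 74 & df$atom == "O"] <- o74[1]
      df$y[df$resno == 74 & df$atom == "O"] <- o74[2]
      df$z[df$resno == 74 & df$atom == "O"] <- o74[3]
    }
    df
  })
  e2_o33 <- e2_bb[[33]]["O", ]
  ca18 <- e3_ca[18, ]
  if (spec$with_linchpin) {
    cz <- (o74 + e2_o33) / 2
    nh1 <- o74 + 3.0 * .unit(cz - o74)
    nh2 <- e2_o33 + 3.0 * .unit(cz - e2_o33)
    ne <- ca18 + 0.6 * (cz - ca18)
  } else {
    shift <- c(0, 0, 25)
    cz <- ca18 + c(0, 0, 24); nh1 <- cz + c(0.8, 0, 1); nh2 <- cz + c(-0.8, 0, 1)
    ne <- ca18 + shift * 0.8
  }
  rows[[length(rows) + 1L]] <- .atom_rows(
    chains["e3"], 18L, "ARG",
    rbind(CB = ca18 + c(0.4, 0.6, 1.2), CZ = cz, NE = ne, NH1 = nh1, NH2 = nh2))
  do.call(rbind, rows)
}

#' Generate a synthetic ternary-complex structure
#'
#' Builds a three-chain toy complex (ubiquitin stand-in with the real
#' ubiquitin sequence, synthetic E2 with crossover helix 39-54 and Cys25,
#' synthetic E3 with an E2-binding loop) whose Ile44-helix and
#' tail-cysteine distances equal the spec targets, optionally with a planted
#' arginine linchpin bridge, replicated `n_copies` times 150 A apart. Writes
#' both PDB and mmCIF.
#'
#' @param spec a [complex_spec()]
#' @param dir output directory
#' @param prefix file name prefix
#' @param write write PDB/mmCIF files (set FALSE for fast in-memory ensembles)
#' @return list: `complex` (the in-memory `ternary_complex`), `pdb`, `cif`
#'   (paths, NULL when `write = FALSE`), `manifest` (spec + measured
#'   distances), `chains` (role -> chain ids per copy)
#' @export
make_complex <- function(spec, dir = tempdir(), prefix = "synthetic_complex",
                         write = TRUE) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  all_rows <- list()
  chain_sets <- list()
  for (k in seq_len(spec$n_copies)) {
    chains <- c(ub = LETTERS[3 * (k - 1) + 1], e2 = LETTERS[3 * (k - 1) + 2],
                e3 = LETTERS[3 * (k - 1) + 3])
    rows <- .build_copy(spec, chains)
    rows[, c("x")] <- rows$x + 150 * (k - 1)
    all_rows[[k]] <- rows
    chain_sets[[k]] <- chains
  }
  atoms <- do.call(rbind, all_rows)
  cx <- structure(list(complex_id = prefix, atoms = atoms,
                       source = "predicted", roles = NULL, copies = NULL,
                       ub_windows = list()),
                  class = "ternary_complex")
  # re-measure: construction must hit the targets within 0.1 A
  ch1 <- chain_sets[[1]]
  copy1 <- list(ub = ch1[["ub"]], e2 = ch1[["e2"]], e3 = ch1[["e3"]])
  helix <- list(chain = ch1[["e2"]], start = 39L, end = 54L, source = "curated")
  m44 <- ile44_helix_distance(cx, copy1, helix)
  mtail <- tail_cys_distance(cx, copy1, 25L)$dist
  if (abs(m44 - spec$ile44_target_dist) > 0.1 ||
      abs(mtail - spec$tail_target_dist) > 0.1) {
    stop("construction error: measured distances (", round(m44, 2), ", ",
         round(mtail, 2), ") missed the targets")
  }
  pdb <- cif <- NULL
  if (write) {
    pdb <- file.path(dir, paste0(prefix, ".pdb"))
    cif <- file.path(dir, paste0(prefix, ".cif"))
    write_pdb(cx, pdb)
    write_mmcif(cx, cif)
  }
  list(complex = cx, pdb = pdb, cif = cif,
       manifest = c(spec, list(measured_ile44 = m44, measured_tail = mtail)),
       chains = chain_sets)
}

#' Generate a synthetic prediction-confidence file (both dialects)
#'
#' PAE matrix with within-chain blocks at an attenuated background error and
#' inter-chain blocks centred at `interface_error` with small jitter; pLDDT
#' anticorrelated with local PAE; chain-pair ipTM computed from the generated
#' PAE with the package's pTM-style formula.
#'
#' @param chain_sizes named integer vector, chain id -> residue count
#' @param interface_error inter-chain PAE centre, A
#' @param background_error within-chain PAE scale, A
#' @param seed integer seed
#' @param dir output directory
#' @param prefix file prefix
#' @return list: `af3`, `colabfold` (paths), `pae`, `plddt`, `chain_spans`
#' @export
make_confidence <- function(chain_sizes, interface_error, background_error = 4,
                            seed = 1L, dir = tempdir(),
                            prefix = "synthetic_confidence") {
  stopifnot(interface_error >= 0, background_error >= 0)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- sum(chain_sizes)
  ids <- rep(names(chain_sizes), chain_sizes)
  pae <- matrix(0, n, n)
  same <- outer(ids, ids, "==")
  jit <- function(m) abs(m + matrix(rnorm(length(m), 0, 0.1 + 0.05 * mean(m)),
                                    nrow(m)))
  pae[same] <- background_error * 0.3
  pae[!same] <- interface_error
  pae <- jit(pae)
  diag(pae) <- 0
  plddt <- pmin(100, pmax(0, 100 - 2.5 * rowMeans(pae) + rnorm(n, 0, 1)))
  spans <- list(); at <- 1L
  for (ch in names(chain_sizes)) {
    spans[[ch]] <- c(at, at + chain_sizes[[ch]] - 1L)
    at <- at + chain_sizes[[ch]]
  }
  conf <- structure(list(plddt = plddt, pae = pae, chain_spans = spans,
                         chain_pair_iptm = list(), dialect = "af3"),
                    class = "prediction_confidence")
  chs <- names(chain_sizes)
  cpi <- matrix(1, length(chs), length(chs))
  for (i in seq_along(chs)) for (j in seq_along(chs)) {
    if (i != j) cpi[i, j] <- interface_iptm(conf, chs[i], chs[j])
  }
  af3_path <- file.path(dir, paste0(prefix, "_af3.json"))
  cf_path <- file.path(dir, paste0(prefix, "_colabfold.json"))
  jsonlite::write_json(
    list(pae = pae, plddt = plddt, token_chain_ids = ids,
         chain_ids = chs, chain_pair_iptm = cpi),
    af3_path, digits = NA, matrix = "rowmajor")
  jsonlite::write_json(
    list(predicted_aligned_error = pae, plddt = plddt,
         ptm = max(cpi[upper.tri(cpi)]), iptm = max(cpi[upper.tri(cpi)])),
    cf_path, digits = NA, matrix = "rowmajor")
  list(af3 = af3_path, colabfold = cf_path, pae = pae, plddt = plddt,
       chain_spans = spans)
}

#' Generate a synthetic interaction edge table
#'
#' Plants `n_true_edges` E2xE3 edges with experimental scores >= 400, plus
#' `n_low_edges` edges with sub-threshold experimental scores (any-evidence
#' edges), and writes a TSV plus a ground-truth manifest.
#'
#' @param n_e2,n_e3 universe sizes (gene names E2_001..., E3_001...)
#' @param n_true_edges number of qualifying (score >= 400) edges
#' @param n_low_edges number of additional sub-threshold edges
#' @param seed integer seed
#' @param path output TSV path
#' @return list: `path`, `edges` (data.frame), `manifest` (true pair keys,
#'   e2/e3 name vectors)
#' @export
make_edge_table <- function(n_e2, n_e3, n_true_edges, n_low_edges = 0L,
                            seed = 1L, path = tempfile(fileext = ".tsv")) {
  stopifnot(n_true_edges + n_low_edges <= n_e2 * n_e3)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  e2s <- sprintf("E2_%03d", seq_len(n_e2))
  e3s <- sprintf("E3_%03d", seq_len(n_e3))
  all_pairs <- expand.grid(e2 = e2s, e3 = e3s, stringsAsFactors = FALSE)
  pick <- sample.int(nrow(all_pairs), n_true_edges + n_low_edges)
  true_idx <- pick[seq_len(n_true_edges)]
  low_idx <- pick[-seq_len(n_true_edges)]
  edges <- rbind(
    data.frame(protein_a = all_pairs$e2[true_idx],
               protein_b = all_pairs$e3[true_idx],
               experimental_score = sample(400:950, n_true_edges, replace = TRUE),
               stringsAsFactors = FALSE),
    if (length(low_idx)) data.frame(
      protein_a = all_pairs$e2[low_idx], protein_b = all_pairs$e3[low_idx],
      experimental_score = sample(1:399, length(low_idx), replace = TRUE),
      stringsAsFactors = FALSE)
  )
  edges$combined_score <- pmin(999L, edges$experimental_score +
                                 sample(0:50, nrow(edges), replace = TRUE))
  utils::write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  list(path = path, edges = edges,
       manifest = list(
         true_pairs = paste(all_pairs$e2[true_idx], all_pairs$e3[true_idx]),
         low_pairs = paste(all_pairs$e2[low_idx], all_pairs$e3[low_idx]),
         e2s = e2s, e3s = e3s, seed = seed))
}

#' Specification for a synthetic labelled feature table
#'
#' Default sample sizes match the Closed-conformation pair / non-pair table
#' (294 / 273); default linchpin rates are the observed 61.2% / 39.9%.
#'
#' @param n_pairs,n_nonpairs class sizes
#' @param effect_size standardized mean shift applied to every continuous
#'   feature family in the pair class, in its observed direction
#' @param noise_sd multiplier on the per-feature standard deviations
#' @param linchpin_rate_pair,linchpin_rate_nonpair Bernoulli rates
#' @param seed integer seed
#' @return a `feature_table_spec` list
#' @export
feature_table_spec <- function(n_pairs = 294L, n_nonpairs = 273L,
                               effect_size = 0.8, noise_sd = 1.0,
                               linchpin_rate_pair = 0.612,
                               linchpin_rate_nonpair = 0.399, seed = 1L) {
  stopifnot(n_pairs >= 1, n_nonpairs >= 1,
            linchpin_rate_pair >= 0, linchpin_rate_pair <= 1,
            linchpin_rate_nonpair >= 0, linchpin_rate_nonpair <= 1)
  list(n_pairs = as.integer(n_pairs), n_nonpairs = as.integer(n_nonpairs),
       effect_size = effect_size, noise_sd = noise_sd,
       linchpin_rate_pair = linchpin_rate_pair,
       linchpin_rate_nonpair = linchpin_rate_nonpair, seed = as.integer(seed))
}

# base mean, sd and pair-shift direction per feature family
.FEATURE_PARAMS <- list(
  ipsae = c(mean = 0.45, sd = 0.15, dir = +1),
  iptm = c(mean = 0.55, sd = 0.15, dir = +1),
  pdockq = c(mean = 0.30, sd = 0.10, dir = +1),
  pdockq2 = c(mean = 0.40, sd = 0.15, dir = +1),
  dG = c(mean = -18, sd = 6, dir = -1),
  dSASA = c(mean = 1200, sd = 250, dir = +1),
  dSASA_polar = c(mean = 500, sd = 120, dir = +1),
  dSASA_nonpolar = c(mean = 700, sd = 150, dir = +1),
  hbonds_total = c(mean = 6, sd = 2, dir = +1),
  hbonds_unsat = c(mean = 4, sd = 1.5, dir = -1),
  n_interface_residues = c(mean = 30, sd = 8, dir = +1),
  ile44_helix_dist = c(mean = 7.08, sd = 0.8, dir = -1),
  tail_cys_dist = c(mean = 4.60, sd = 0.6, dir = -1),
  n_e3_loops = c(mean = 2, sd = 0.8, dir = +1),
  n_e3_loop_residues = c(mean = 8, sd = 3, dir = +1)
)

#' Generate a labelled synthetic feature table
#'
#' Pairs are drawn with shifted means in the observed effect directions
#' (higher confidence scores, lower distances, fewer unsatisfied hydrogen
#' bonds, higher linchpin rate); Gaussian noise elsewhere. Scores are clamped
#' to `[0, 1]`, counts rounded and floored at 0.
#'
#' @param spec a [feature_table_spec()]
#' @return list: `table` (data.frame with complex_id, e2, e3, label,
#'   prefilter columns and the 38 features), `manifest`
#' @export
make_feature_table <- function(spec = feature_table_spec()) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  n <- spec$n_pairs + spec$n_nonpairs
  is_pair <- c(rep(1, spec$n_pairs), rep(0, spec$n_nonpairs))
  tab <- data.frame(
    complex_id = sprintf("CPLX_%04d", seq_len(n)),
    e2 = sprintf("E2_%03d", sample.int(31, n, replace = TRUE)),
    e3 = sprintf("E3_%03d", sample.int(146, n, replace = TRUE)),
    label = ifelse(is_pair == 1, "pair", "nonpair"),
    stringsAsFactors = FALSE
  )
  fam_of <- function(col) {
    if (col %in% .COMPLEX_FEATURES) return(col)
    sub("^(ub_e2|ub_e3|e2_e3)_", "", col)
  }
  for (col in setdiff(feature_schema(), "linchpin_flag")) {
    p <- .FEATURE_PARAMS[[fam_of(col)]]
    mu <- p["mean"] + is_pair * p["dir"] * spec$effect_size * p["sd"]
    v <- rnorm(n, mu, p["sd"] * spec$noise_sd)
    if (fam_of(col) %in% c("ipsae", "iptm", "pdockq", "pdockq2")) {
      v <- pmin(1, pmax(0, v))
    }
    if (fam_of(col) %in% c("hbonds_total", "hbonds_unsat", "n_e3_loops",
                           "n_e3_loop_residues", "n_interface_residues")) {
      v <- pmax(0, round(v))
    }
    if (fam_of(col) %in% c("ile44_helix_dist", "tail_cys_dist")) {
      v <- pmax(0.1, v)
    }
    tab[[col]] <- as.numeric(v)
  }
  rate <- ifelse(is_pair == 1, spec$linchpin_rate_pair,
                 spec$linchpin_rate_nonpair)
  tab$linchpin_flag <- as.numeric(runif(n) < rate)
  tab$conformation <- "Closed"
  tab$ring_engagement <- 1
  tab$ptm <- pmin(1, pmax(0, (tab$ub_e2_iptm + tab$ub_e3_iptm + tab$e2_e3_iptm) / 3))
  tab$iptm <- tab$e2_e3_iptm
  list(table = tab, manifest = spec)
}

#' Generate a synthetic per-interface energetics table
#'
#' One row per (complex, interface) in the external-tool TSV contract, with
#' controllable pair/non-pair effect (pairs get fewer unsatisfied hydrogen
#' bonds and more favourable binding energies).
#'
#' @param complex_ids character vector
#' @param is_pair logical/0-1 vector aligned with `complex_ids`
#' @param effect_size standardized shift
#' @param seed integer seed
#' @param path optional TSV output path
#' @return data.frame (written to `path` when given)
#' @export
make_energetics_table <- function(complex_ids, is_pair,
                                  effect_size = 0.8, seed = 1L, path = NULL) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  grid <- expand.grid(complex_id = complex_ids,
                      interface = names(.IFACE_TAGS),
                      stringsAsFactors = FALSE)
  pairflag <- is_pair[match(grid$complex_id, complex_ids)]
  n <- nrow(grid)
  dsasa <- pmax(200, rnorm(n, 1200 + 100 * effect_size * pairflag, 250))
  polar <- pmin(dsasa * 0.6, pmax(50, rnorm(n, 500, 120)))
  out <- data.frame(
    grid,
    dG = rnorm(n, -18 - 4 * effect_size * pairflag, 6),
    dSASA = dsasa,
    dSASA_polar = polar,
    dSASA_nonpolar = pmax(0, dsasa - polar),
    hbonds_int = pmax(0, round(rnorm(n, 6 + effect_size * pairflag, 2))),
    hbonds_unsat = pmax(0, round(rnorm(n, 4 - effect_size * pairflag, 1.5))),
    nres = pmax(2, round(rnorm(n, 30, 8))),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
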