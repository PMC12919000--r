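# Shared fixtures and independent brute-force oracles. Oracles are written
# plainly (double loops) and never call the implementation they check.

test_registry <- function() {
  read_registry(system.file("extdata", "synthetic_registry.tsv",
                            package = "ubiqpair"))
}

ROLE_OVERRIDES <- c(A = "UB", B = "E2", C = "E3")

# Build a ternary_complex directly from an atom table.
micro_complex <- function(atoms, source = "experimental", id = "micro") {
  defaults <- list(ins = "", altloc = "", occ = 1, het = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  }
  if (!"element" %in% names(atoms)) {
    atoms$element <- substr(gsub("[0-9]", "", atoms$atom), 1, 1)
  }
  structure(list(complex_id = id, atoms = atoms, source = source,
                 roles = NULL, copies = NULL, ub_windows = list()),
            class = "ternary_complex")
}

atomdf <- function(chain, resno, resname, atom, x, y, z) {
  data.frame(chain = chain, resno = as.integer(resno), resname = resname,
             atom = atom, x = x, y = y, z = z, stringsAsFactors = FALSE)
}

# chain of CA-only residues along given coordinates (n x 3 matrix)
ca_chain <- function(chain, xyz, resname = "ALA", start_resno = 1L) {
  n <- nrow(xyz)
  atomdf(chain, seq.int(start_resno, length.out = n),
         rep(resname, length.out = n), "CA", xyz[, 1], xyz[, 2], xyz[, 3])
}

ideal_helix <- function(n, origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1
  th <- 100 * i * pi / 180
  cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i) +
    matrix(origin, n, 3, byrow = TRUE)
}

# a synthetic complex with roles/copies assigned via overrides (fast path)
assigned_synthetic <- function(spec, refs = test_registry()) {
  res <- make_complex(spec, write = FALSE)
  ov <- stats::setNames(rep(c("UB", "E2", "E3"), spec$n_copies),
                        LETTERS[seq_len(3 * spec$n_copies)])
  enumerate_copies(assign_roles(res$complex, refs, overrides = ov))
}

## ---- independent oracles -------------------------------------------------

oracle_interface <- function(ca_a, ca_b, resno_a, resno_b, cutoff = 8) {
  keep_a <- c(); keep_b <- c()
  for (i in seq_len(nrow(ca_a))) for (j in seq_len(nrow(ca_b))) {
    d <- sqrt(sum((ca_a[i, ] - ca_b[j, ])^2))
    if (d < cutoff) { keep_a <- c(keep_a, resno_a[i]); keep_b <- c(keep_b, resno_b[j]) }
  }
  list(a = sort(unique(keep_a)), b = sort(unique(keep_b)))
}

oracle_hbonds <- function(at_a, at_b, cutoff = 3.5) {
  if (is.null(at_a$element)) at_a$element <- substr(gsub("[0-9]", "", at_a$atom), 1, 1)
  if (is.null(at_b$element)) at_b$element <- substr(gsub("[0-9]", "", at_b$atom), 1, 1)
  n <- 0L
  for (i in seq_len(nrow(at_a))) {
    if (!at_a$element[i] %in% c("N", "O")) next
    for (j in seq_len(nrow(at_b))) {
      if (!at_b$element[j] %in% c("N", "O")) next
      d <- sqrt((at_a$x[i] - at_b$x[j])^2 + (at_a$y[i] - at_b$y[j])^2 +
                  (at_a$z[i] - at_b$z[j])^2)
      if (d <= cutoff) n <- n + 1L
    }
  }
  n
}

oracle_d0 <- function(n, floor = 1.0) max(floor, 1.24 * (max(n, 19) - 15)^(1/3) - 1.8)

oracle_ipsae <- function(pae, ia, ib, thr = 10, floor = 1.0) {
  one <- function(rows, cols) {
    vals <- c(); scored <- c()
    for (i in rows) for (j in cols) {
      if (pae[i, j] < thr) { vals <- c(vals, pae[i, j]); scored <- c(scored, i) }
    }
    if (!length(vals)) return(0)
    d0 <- oracle_d0(length(unique(scored)), floor)
    mean(1 / (1 + (vals / d0)^2))
  }
  max(one(ia, ib), one(ib, ia))
}

oracle_mean_pae <- function(pae, ia, ib) {
  if (!length(ia) || !length(ib)) return(NA_real_)
  vals <- c()
  for (i in ia) for (j in ib) vals <- c(vals, pae[i, j], pae[j, i])
  mean(vals)
}

oracle_pdockq2 <- function(pae, plddt, ia, ib) {
  if (!length(ia) || !length(ib)) return(NA_real_)
  terms <- c()
  for (i in ia) for (j in ib) {
    terms <- c(terms, 1 / (1 + (pae[i, j] / 10)^2), 1 / (1 + (pae[j, i] / 10)^2))
  }
  x <- mean(plddt[c(ia, ib)]) * mean(terms)
  1.31034849 / (1 + exp(-0.075 * (x - 84.733))) + 0.005
}

oracle_fbeta_threshold <- function(probs, labels, beta = 0.75) {
  best_t <- NA; best_f <- -Inf
  for (t in sort(unique(probs))) {
    pred <- probs >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (prec + rec > 0) (1 + beta^2) * prec * rec / (beta^2 * prec + rec) else 0
    if (f > best_f + 1e-12) { best_f <- f; best_t <- t }
  }
  best_t
}

random_rot <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
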