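# Small shared helpers: residue bookkeeping, geometry, amino-acid codes.

.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)
.AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

aa3to1 <- function(x) {
  out <- .AA3TO1[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Ordered residue table for one chain: one row per residue, in file order.
residue_table <- function(complex, chain) {
  at <- complex$atoms[complex$atoms$chain == chain & !complex$atoms$het, , drop = FALSE]
  if (nrow(at) == 0) {
    return(data.frame(resno = integer(), ins = character(), resname = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(at$resno, at$ins, sep = "\r")
  first <- !duplicated(key)
  data.frame(resno = at$resno[first], ins = at$ins[first],
             resname = at$resname[first], stringsAsFactors = FALSE)
}

chain_sequence <- function(complex, chain) {
  rt <- residue_table(complex, chain)
  paste0(aa3to1(rt$resname), collapse = "")
}

# Coordinates of one named atom for every residue of a chain, NA if missing.
atom_coords <- function(complex, chain, atom = "CA", resno = NULL) {
  at <- complex$atoms
  sel <- at$chain == chain & at$atom == atom & !at$het
  if (!is.null(resno)) sel <- sel & at$resno %in% resno
  at <- at[sel, , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- NULL
  list(resno = at$resno, xyz = m)
}

# Calpha matrix in residue order for a chain (rows named by author resno).
ca_matrix <- function(complex, chain) {
  rt <- residue_table(complex, chain)
  at <- complex$atoms
  m <- matrix(NA_real_, nrow(rt), 3)
  for (i in seq_len(nrow(rt))) {
    sel <- at$chain == chain & at$resno == rt$resno[i] & at$ins == rt$ins[i] &
      at$atom == "CA" & !at$het
    if (any(sel)) m[i, ] <- as.numeric(at[which(sel)[1], c("x", "y", "z")])
  }
  rownames(m) <- as.character(rt$resno)
  m
}

# Heavy atoms (non-H) of a chain, optionally restricted to residue numbers.
heavy_atoms <- function(complex, chain, resno = NULL) {
  at <- complex$atoms
  sel <- at$chain == chain & !at$het & at$element != "H"
  if (!is.null(resno)) sel <- sel & at$resno %in% resno
  at[sel, , drop = FALSE]
}

# All pairwise Euclidean distances between rows of two coordinate matrices.
cross_dist <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 3)
  if (!is.matrix(b)) b <- matrix(b, ncol = 3)
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Apply a rigid transform (3x3 rotation R, 3-vector t) to a complex in place.
#' Apply a rigid-body transform to all atoms of a complex
#'
#' Rotates and translates every atom: x' = R x + t. Used mainly by the
#' invariance tests and the fixture generators.
#'
#' @param complex a `ternary_complex`
#' @param R 3x3 rotation matrix
#' @param t length-3 translation vector
#' @return the transformed `ternary_complex`
#' @export
transform_complex <- function(complex, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(complex$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(R) + matrix(t, nrow(xyz), 3, byrow = TRUE)
  complex$atoms$x <- xyz[, 1]
  complex$atoms$y <- xyz[, 2]
  complex$atoms$z <- xyz[, 3]
  complex
}

# Random rotation matrix (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Kabsch superposition: rotation/translation mapping `mobile` onto `fixed`
# (both n x 3, paired rows), minimising RMSD.
kabsch <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed), nrow(mobile) >= 3)
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, t = as.numeric(cf - R %*% cm))
}

apply_rt <- function(xyz, rt) {
  xyz %*% t(rt$R) + matrix(rt$t, nrow(xyz), 3, byrow = TRUE)
}
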