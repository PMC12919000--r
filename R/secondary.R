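# Calpha-geometry secondary-structure detection: enough to find the E2
# crossover helix and to separate loops from helices/strands on the E3. Not a
# DSSP replacement (no hydrogen bonds, no angle criteria).

# Per-residue flags from Calpha coordinates (rows in residue order, NA rows
# allowed). Helix window test at i: d(i,i+3) in [4.5, 6.0] and d(i,i+4) in
# [5.8, 7.1]; a passing window flags residues i..i+4. Strand window test at i:
# d(i,i+2) >= 6.2 and d(i,i+3) >= 9.0 (extended); flags i..i+2.
ss_flags <- function(ca) {
  n <- nrow(ca)
  helix <- logical(n); strand <- logical(n)
  d <- function(i, j) sqrt(sum((ca[i, ] - ca[j, ])^2))
  # windows containing a chain break (consecutive Calpha gap > 4.5 A, e.g.
  # unresolved residues) carry no secondary-structure information
  contiguous <- function(i, j) {
    for (k in i:(j - 1)) {
      if (anyNA(ca[k:(k + 1), ]) || d(k, k + 1) > 4.5) return(FALSE)
    }
    TRUE
  }
  for (i in seq_len(max(0, n - 4))) {
    if (anyNA(ca[i:(i + 4), ]) || !contiguous(i, i + 4)) next
    d3 <- d(i, i + 3); d4 <- d(i, i + 4)
    if (d3 >= 4.5 && d3 <= 6.0 && d4 >= 5.8 && d4 <= 7.1) helix[i:(i + 4)] <- TRUE
  }
  for (i in seq_len(max(0, n - 3))) {
    if (anyNA(ca[i:(i + 3), ]) || !contiguous(i, i + 3)) next
    if (d(i, i + 2) >= 6.2 && d(i, i + 3) >= 9.0) strand[i:(i + 3)] <- TRUE
  }
  strand[helix] <- FALSE
  list(helix = helix, strand = strand)
}

# Maximal runs of TRUE in a logical vector: data.frame(start, end) of indices.
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Locate the E2 crossover helix
#'
#' Returns the curated registry span when one is supplied; otherwise detects
#' the first alpha-helix of length >= 6 that begins after the catalytic
#' cysteine, using Calpha-geometry helix detection.
#'
#' @param complex a `ternary_complex`
#' @param chain E2 chain id
#' @param curated optional length-2 integer vector `c(start, end)` of author
#'   residue numbers (curated annotation; takes precedence)
#' @param cys_resno author residue number of the catalytic cysteine (required
#'   for detection, ignored when `curated` is given)
#' @return list with `chain`, `start`, `end` (author numbering), `source`
#'   (`"curated"` or `"detected"`)
#' @export
find_crossover_helix <- function(complex, chain, curated = NULL, cys_resno = NULL) {
  if (!is.null(curated)) {
    stopifnot(length(curated) == 2, curated[1] <= curated[2])
    if (curated[2] - curated[1] + 1 < 6) stop("curated helix span shorter than 6 residues")
    return(list(chain = chain, start = as.integer(curated[1]),
                end = as.integer(curated[2]), source = "curated"))
  }
  ca <- ca_matrix(complex, chain)
  if (sum(stats::complete.cases(ca)) < 20) {
    stop("chain ", chain, " has fewer than 20 residues with Calpha coordinates")
  }
  fl <- ss_flags(ca)
  segs <- .runs(fl$helix)
  segs <- segs[segs$end - segs$start + 1 >= 6, , drop = FALSE]
  resno <- as.integer(rownames(ca))
  if (!is.null(cys_resno)) {
    cys_idx <- match(cys_resno, resno)
    if (is.na(cys_idx)) stop("catalytic cysteine residue ", cys_resno, " not found")
    segs <- segs[segs$start > cys_idx, , drop = FALSE]
  }
  if (nrow(segs) == 0) {
    stop("no crossover helix detected after the catalytic cysteine; ",
         "supply a curated span in the registry")
  }
  list(chain = chain, start = resno[segs$start[1]], end = resno[segs$end[1]],
       source = "detected")
}

#' Identify the E3-interacting loop of an E2
#'
#' The coil region immediately N-terminal of the crossover helix: the maximal
#' contiguous non-helix, non-strand segment ending at `helix$start - 1`,
#' bounded by the nearest upstream secondary-structure element or 12 residues,
#' whichever is shorter. A curated span overrides detection.
#'
#' @param complex a `ternary_complex`
#' @param helix crossover helix from [find_crossover_helix()]
#' @param curated optional `c(start, end)` override (author numbering)
#' @param max_len cap on loop length (default 12 residues)
#' @return integer vector `c(start, end)` in author numbering; zero-length
#'   span (with a warning) when the helix starts the chain
#' @export
find_e2_binding_loop <- function(complex, helix, curated = NULL, max_len = 12L) {
  if (!is.null(curated)) return(as.integer(curated))
  ca <- ca_matrix(complex, helix$chain)
  resno <- as.integer(rownames(ca))
  h_idx <- match(helix$start, resno)
  if (is.na(h_idx)) stop("helix start residue not present in chain")
  if (h_idx == 1L) {
    warning("crossover helix starts at the chain start; empty binding loop")
    return(integer(0))
  }
  fl <- ss_flags(ca)
  ss <- fl$helix | fl$strand
  # treat the helix span itself as SS regardless of per-window flags
  ss[resno >= helix$start & resno <= helix$end] <- TRUE
  i <- h_idx - 1L
  start <- i
  while (start > 1L && !ss[start - 1L] && (i - start + 1L) < max_len) {
    start <- start - 1L
  }
  if (ss[i]) {
    warning("no coil residue immediately N-terminal of the helix; empty loop")
    return(integer(0))
  }
  c(resno[start], resno[i])
}
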