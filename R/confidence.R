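# Interface-level confidence metrics derived from prediction-confidence files:
# mean interface PAE, ipSAE, pDockQ, pDockQ2 and chain-pair ipTM.

#' Load a prediction-confidence JSON file
#'
#' Two dialects are supported. `af3`: an object with `pae` (square matrix),
#' `plddt` (per-residue), `token_chain_ids` (per-residue chain id) and
#' optionally `chain_pair_iptm` (matrix in `chain_ids` order). `colabfold`:
#' an object with `predicted_aligned_error` and `plddt` but no chain
#' assignment, so `chain_spans` must be supplied (named list,
#' chain id -> c(start, end) global residue indices).
#'
#' @param path JSON file
#' @param dialect `"af3"` or `"colabfold"`
#' @param chain_spans required for the colabfold dialect; optional consistency
#'   check for af3
#' @param n_residues optional expected residue count (e.g. from the structure);
#'   a mismatch raises an alignment error
#' @return a `prediction_confidence` list: `plddt`, `pae`, `chain_spans`,
#'   `chain_pair_iptm` (named list "A:B" -> value, possibly empty), `dialect`
#' @export
load_confidence <- function(path, dialect = c("af3", "colabfold"),
                            chain_spans = NULL, n_residues = NULL) {
  dialect <- match.arg(dialect)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (dialect == "af3") {
    pae <- as.matrix(js$pae)
    plddt <- as.numeric(js$plddt)
    if (is.null(js$token_chain_ids)) stop("af3 file lacks token_chain_ids")
    tok <- as.character(js$token_chain_ids)
    spans <- lapply(split(seq_along(tok), factor(tok, levels = unique(tok))),
                    range)
    cpi <- list()
    if (!is.null(js$chain_pair_iptm)) {
      ids <- as.character(js$chain_ids %||% names(spans))
      m <- as.matrix(js$chain_pair_iptm)
      for (i in seq_along(ids)) for (j in seq_along(ids)) {
        if (i != j) cpi[[paste(ids[i], ids[j], sep = ":")]] <- m[i, j]
      }
    }
  } else {
    pae <- as.matrix(js$predicted_aligned_error %||% js$pae)
    plddt <- as.numeric(js$plddt)
    if (is.null(chain_spans)) stop("colabfold dialect requires chain_spans")
    spans <- lapply(chain_spans, function(s) as.integer(s))
    cpi <- list()
  }
  if (nrow(pae) != ncol(pae)) stop("alignment error: PAE matrix not square")
  n <- nrow(pae)
  if (length(plddt) != n) {
    stop("alignment error: pLDDT length ", length(plddt),
         " does not match PAE dimension ", n)
  }
  if (!is.null(n_residues) && n_residues != n) {
    stop("alignment error: PAE dimension ", n,
         " does not match structure residue count ", n_residues)
  }
  tot <- sum(vapply(spans, function(s) s[2] - s[1] + 1L, 1L))
  if (tot != n) stop("alignment error: chain spans sum to ", tot, ", PAE is ", n)
  structure(list(plddt = plddt, pae = unname(pae), chain_spans = spans,
                 chain_pair_iptm = cpi, dialect = dialect),
            class = "prediction_confidence")
}

#' Score parameters for PAE-based metrics
#' @param pae_threshold PAE inclusion cutoff in Angstrom (default 10)
#' @param d0_floor lower clamp for the TM-score size law (default 1.0)
#' @param interface_cutoff interface Calpha cutoff in Angstrom (default 8)
#' @return a `score_params` list
#' @export
score_params <- function(pae_threshold = .PAE_THRESHOLD, d0_floor = .D0_FLOOR,
                         interface_cutoff = .INTERFACE_CUTOFF) {
  stopifnot(pae_threshold > 0)
  list(pae_threshold = pae_threshold, d0_floor = d0_floor,
       interface_cutoff = interface_cutoff)
}

.span_idx <- function(conf, chain) {
  s <- conf$chain_spans[[chain]]
  if (is.null(s)) stop("unknown chain in confidence file: ", chain)
  seq.int(s[1], s[2])
}

# Global residue indices of interface members on one chain, given an
# interface residue set (data.frame chain/resno) and the residue order of the
# structure chain.
.iface_global_idx <- function(conf, chain, iface, chain_resno) {
  idx <- .span_idx(conf, chain)
  memb <- iface$resno[iface$chain == chain]
  pos <- match(memb, chain_resno)
  idx[pos[!is.na(pos)]]
}

#' Mean interface PAE for a chain pair
#'
#' Mean of `pae[i, j]` and `pae[j, i]` over all inter-chain residue pairs in
#' which both residues are interface members (8 A Calpha rule). Absent (`NA`)
#' when the interface is empty.
#'
#' @param conf a `prediction_confidence`
#' @param idx_a,idx_b global residue indices of the interface members on each
#'   chain (see [interface_residues()]; indices into the PAE matrix)
#' @return mean PAE in Angstrom, or `NA_real_`
#' @export
mean_interface_pae <- function(conf, idx_a, idx_b) {
  if (length(idx_a) == 0 || length(idx_b) == 0) return(NA_real_)
  mean(c(conf$pae[idx_a, idx_b, drop = FALSE],
         conf$pae[idx_b, idx_a, drop = FALSE]))
}

#' ipSAE interface score for a chain pair
#'
#' For each alignment direction, inter-chain residue pairs with
#' `PAE < pae_threshold` are averaged under the TM-score-style transform
#' `1 / (1 + (PAE/d0)^2)`, where `d0` is computed from the number of
#' scored-chain residues participating in at least one qualifying pair via
#' `d0(n) = max(d0_floor, 1.24 (n-15)^(1/3) - 1.8)`. The aggregate is the
#' maximum over the two directions; 0 when no pair qualifies.
#'
#' @param conf a `prediction_confidence`
#' @param chain_a,chain_b chain ids
#' @param params a [score_params()] list
#' @return list: `ab`, `ba` (per-direction values), `value` (max)
#' @export
ipsae <- function(conf, chain_a, chain_b, params = score_params()) {
  ia <- .span_idx(conf, chain_a); ib <- .span_idx(conf, chain_b)
  one_dir <- function(rows, cols) {
    block <- conf$pae[rows, cols, drop = FALSE]
    qual <- block < params$pae_threshold
    if (!any(qual)) return(0)
    n_scored <- sum(rowSums(qual) > 0)
    d0 <- .d0_law(n_scored, params$d0_floor)
    mean(1 / (1 + (block[qual] / d0)^2))
  }
  ab <- one_dir(ia, ib)
  ba <- one_dir(ib, ia)
  list(ab = ab, ba = ba, value = max(ab, ba))
}

#' pDockQ2 interface-quality score
#'
#' Sigmoid of `x = mean interface pLDDT * mean PAE term`, where the PAE term
#' is `1/(1+(PAE/10)^2)` averaged over inter-chain interface residue pairs
#' (both orientations). Constants from the reference implementation (see
#' R/constants.R). Absent when the interface is empty.
#'
#' @param conf a `prediction_confidence`
#' @param idx_a,idx_b global residue indices of interface members on the two
#'   chains
#' @return score in (0, 1), or `NA_real_` for an empty interface
#' @export
pdockq2 <- function(conf, idx_a, idx_b) {
  if (length(idx_a) == 0 || length(idx_b) == 0) return(NA_real_)
  mean_plddt <- mean(conf$plddt[c(idx_a, idx_b)])
  pae_vals <- c(conf$pae[idx_a, idx_b, drop = FALSE],
                conf$pae[idx_b, idx_a, drop = FALSE])
  ptm_term <- mean(1 / (1 + (pae_vals / .PDOCKQ2_D0)^2))
  x <- mean_plddt * ptm_term
  .PDOCKQ2_L / (1 + exp(-.PDOCKQ2_K * (x - .PDOCKQ2_X0))) + .PDOCKQ2_B
}

#' pDockQ (version 1) interface score
#'
#' `x = mean interface pLDDT * log(n_contacts)` passed through the original
#' sigmoid; contacts are inter-chain interface residue pairs within the 8 A
#' Calpha rule.
#'
#' @param conf a `prediction_confidence`
#' @param idx_a,idx_b global residue indices of interface members
#' @param n_contacts number of inter-chain residue contacts
#' @return score in (0, 1), or `NA_real_` when there are no contacts
#' @export
pdockq <- function(conf, idx_a, idx_b, n_contacts) {
  if (n_contacts <= 0 || length(idx_a) == 0 || length(idx_b) == 0) {
    return(NA_real_)
  }
  x <- mean(conf$plddt[c(idx_a, idx_b)]) * log(n_contacts)
  .PDOCKQ_L / (1 + exp(-.PDOCKQ_K * (x - .PDOCKQ_X0))) + .PDOCKQ_B
}

#' Chain-pair ipTM
#'
#' For the af3 dialect, returns the stored chain-pair value (max over the two
#' orientations). For the colabfold dialect, computes a pairwise pTM-style
#' score from the PAE matrix: per aligned residue i of one chain, the mean of
#' `1/(1+(PAE[i,j]/d0)^2)` over all residues j of the other chain, with d0
#' from the total residue count of the chain pair; the score is the maximum
#' over aligned residues in both directions.
#'
#' @param conf a `prediction_confidence`
#' @param chain_a,chain_b chain ids
#' @param d0_floor lower clamp for the size law
#' @return value in `[0, 1]`
#' @export
interface_iptm <- function(conf, chain_a, chain_b, d0_floor = .D0_FLOOR) {
  k1 <- paste(chain_a, chain_b, sep = ":")
  k2 <- paste(chain_b, chain_a, sep = ":")
  stored <- c(conf$chain_pair_iptm[[k1]], conf$chain_pair_iptm[[k2]])
  if (length(stored) > 0) return(max(unlist(stored)))
  if (is.null(conf$pae)) stop("ipTM unavailable: no stored value and no PAE")
  ia <- .span_idx(conf, chain_a); ib <- .span_idx(conf, chain_b)
  d0 <- .d0_law(length(ia) + length(ib), d0_floor)
  ab <- max(rowMeans(1 / (1 + (conf$pae[ia, ib, drop = FALSE] / d0)^2)))
  ba <- max(rowMeans(1 / (1 + (conf$pae[ib, ia, drop = FALSE] / d0)^2)))
  max(ab, ba)
}

#' Confidence record for one interface of a complex
#'
#' Convenience wrapper computing the full set of per-interface confidence
#' metrics given the structure-derived interface residue set.
#'
#' @param conf a `prediction_confidence`
#' @param complex a `ternary_complex`
#' @param copy one copy
#' @param pair interface name (`"UB-E2"`, `"UB-E3"`, `"E2-E3"`)
#' @param params a [score_params()] list
#' @return one-row data.frame: interface, iptm, mean_interface_pae, ipsae,
#'   pdockq, pdockq2, n_interface_residues
#' @export
confidence_record <- function(conf, complex, copy, pair,
                              params = score_params()) {
  ch <- .iface_chains(copy, pair)
  iface <- interface_residues(complex, copy, pair, params$interface_cutoff)
  resno_a <- residue_table(complex, ch[1])$resno
  resno_b <- residue_table(complex, ch[2])$resno
  idx_a <- .iface_global_idx(conf, ch[1], iface, resno_a)
  idx_b <- .iface_global_idx(conf, ch[2], iface, resno_b)
  # contact count for pDockQ: inter-chain residue pairs within the cutoff
  a <- atom_coords(complex, ch[1], "CA"); b <- atom_coords(complex, ch[2], "CA")
  n_contacts <- sum(cross_dist(a$xyz, b$xyz) < params$interface_cutoff)
  data.frame(
    interface = pair,
    iptm = interface_iptm(conf, ch[1], ch[2], params$d0_floor),
    mean_interface_pae = mean_interface_pae(conf, idx_a, idx_b),
    ipsae = ipsae(conf, ch[1], ch[2], params)$value,
    pdockq = pdockq(conf, idx_a, idx_b, n_contacts),
    pdockq2 = pdockq2(conf, idx_a, idx_b),
    n_interface_residues = nrow(iface),
    stringsAsFactors = FALSE
  )
}
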