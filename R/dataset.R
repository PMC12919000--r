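# E3 domain classification, RING/U-box truncation spans, and construction of
# labelled pair / non-pair E2-E3 sets from a physical-interaction edge table.

#' Classify an E3 ligase from its domain content
#'
#' Rules: HECT present -> HECT; U-box present -> UBOX; RING with IBR -> RBR;
#' RING without IBR -> RING; RING and HECT together -> ATYPICAL; none of the
#' above -> NONE. Precedence when several rules fire: ATYPICAL > HECT > UBOX >
#' RBR > RING.
#'
#' @param domains data.frame with at least a `kind` column (values among RING,
#'   UBOX, HECT, IBR); may have zero rows
#' @return one of "RING", "UBOX", "HECT", "RBR", "ATYPICAL", "NONE"
#' @export
classify_e3 <- function(domains) {
  kinds <- unique(toupper(domains$kind %||% character(0)))
  has <- function(k) k %in% kinds
  if (has("RING") && has("HECT")) return("ATYPICAL")
  if (has("HECT")) return("HECT")
  if (has("UBOX")) return("UBOX")
  if (has("RING") && has("IBR")) return("RBR")
  if (has("RING")) return("RING")
  "NONE"
}

#' RING/U-box truncation span for an E3
#'
#' The span is `[min start, max end]` over all RING/U-box ECOD domains, each
#' expanded to the union with any overlapping TED domain. When no ECOD
#' RING/U-box exists, PROSITE RING/U-box spans are used. Multiple domains are
#' merged into one covering span.
#'
#' @param domains data.frame with columns `kind`, `source` (ECOD/TED/PROSITE),
#'   `start`, `end`
#' @return integer `c(start, end)`
#' @export
build_truncation <- function(domains) {
  domains$kind <- toupper(domains$kind)
  domains$source <- toupper(domains$source)
  ru <- domains[domains$kind %in% c("RING", "UBOX"), , drop = FALSE]
  ecod <- ru[ru$source == "ECOD", , drop = FALSE]
  ted <- domains[domains$source == "TED", , drop = FALSE]
  spans <- NULL
  if (nrow(ecod) > 0) {
    spans <- lapply(seq_len(nrow(ecod)), function(i) {
      s <- ecod$start[i]; e <- ecod$end[i]
      ov <- ted[ted$start <= e & ted$end >= s, , drop = FALSE]
      if (nrow(ov) > 0) c(min(s, ov$start), max(e, ov$end)) else c(s, e)
    })
  } else {
    pros <- ru[ru$source == "PROSITE", , drop = FALSE]
    if (nrow(pros) == 0) stop("no RING/U-box domain from any source")
    spans <- lapply(seq_len(nrow(pros)), function(i) c(pros$start[i], pros$end[i]))
  }
  m <- do.call(rbind, spans)
  c(as.integer(min(m[, 1])), as.integer(max(m[, 2])))
}

#' Build the pair set from an interaction edge table
#'
#' Keeps every E2 x E3 edge with `experimental_score >= min_score`, labels it
#' "pair" and deduplicates across edge direction.
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`,
#'   `experimental_score` (and optionally `combined_score`)
#' @param e2_list,e3_list character vectors of gene names
#' @param min_score inclusive threshold (default 400)
#' @return data.frame: e2, e3, label, evidence_score, provenance
#' @export
build_pair_set <- function(edges, e2_list, e3_list, min_score = 400L) {
  a_is_e2 <- edges$protein_a %in% e2_list & edges$protein_b %in% e3_list
  b_is_e2 <- edges$protein_b %in% e2_list & edges$protein_a %in% e3_list
  df <- rbind(
    data.frame(e2 = edges$protein_a[a_is_e2], e3 = edges$protein_b[a_is_e2],
               score = edges$experimental_score[a_is_e2], stringsAsFactors = FALSE),
    data.frame(e2 = edges$protein_b[b_is_e2], e3 = edges$protein_a[b_is_e2],
               score = edges$experimental_score[b_is_e2], stringsAsFactors = FALSE)
  )
  if (nrow(df) > 0) {
    # deduplicate directions, keeping the best score per combination
    df <- df[order(df$e2, df$e3, -df$score), , drop = FALSE]
    df <- df[!duplicated(df[, c("e2", "e3")]), , drop = FALSE]
    df <- df[df$score >= min_score, , drop = FALSE]
  }
  if (nrow(df) == 0) warning("no qualifying edges at min_score = ", min_score)
  data.frame(e2 = df$e2, e3 = df$e3, label = rep("pair", nrow(df)),
             evidence_score = as.integer(df$score),
             provenance = rep(sprintf("experimental_score>=%d", min_score),
                              nrow(df)),
             stringsAsFactors = FALSE)
}

#' Candidate non-pair pool for a pair set
#'
#' The Cartesian product of the unique E2s and unique E3s of the pair set,
#' minus every combination with any edge at any evidence level
#' (`combined_score > 0`), minus the pair set itself.
#'
#' @param pair_set output of [build_pair_set()]
#' @param edges the full edge table
#' @return data.frame with columns `e2`, `e3`
#' @export
nonpair_candidate_pool <- function(pair_set, edges) {
  e2s <- sort(unique(pair_set$e2)); e3s <- sort(unique(pair_set$e3))
  pool <- expand.grid(e2 = e2s, e3 = e3s, stringsAsFactors = FALSE)
  comb <- edges$combined_score %||% edges$experimental_score
  any_ev <- comb > 0
  evid <- unique(c(paste(edges$protein_a[any_ev], edges$protein_b[any_ev]),
                   paste(edges$protein_b[any_ev], edges$protein_a[any_ev])))
  key <- paste(pool$e2, pool$e3)
  pool <- pool[!(key %in% evid), , drop = FALSE]
  key <- paste(pool$e2, pool$e3)
  pool[!(key %in% paste(pair_set$e2, pair_set$e3)), , drop = FALSE]
}

#' Sample the non-pair set
#'
#' Deterministic uniform sample of `n` combinations from the candidate pool
#' given `seed`.
#'
#' @inheritParams nonpair_candidate_pool
#' @param n sample size (typically `nrow(pair_set)`)
#' @param seed integer seed, recorded in the output provenance
#' @return data.frame: e2, e3, label ("nonpair"), evidence_score (NA),
#'   provenance
#' @export
build_nonpair_set <- function(pair_set, edges, n, seed) {
  if (nrow(pair_set) == 0) stop("pair set is empty")
  pool <- nonpair_candidate_pool(pair_set, edges)
  if (nrow(pool) < n) {
    stop("candidate pool (", nrow(pool), ") smaller than requested n = ", n)
  }
  pool <- pool[order(pool$e2, pool$e3), , drop = FALSE]
  idx <- withr_seed_sample(nrow(pool), n, seed)
  out <- pool[idx, , drop = FALSE]
  rownames(out) <- NULL
  out$label <- "nonpair"
  out$evidence_score <- NA_integer_
  out$provenance <- sprintf("uniform sample, seed=%d", seed)
  out
}

# Seeded sample that does not disturb the caller's RNG state.
withr_seed_sample <- function(pool_size, n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(pool_size, n)
}

#' Default exclusion policy
#'
#' HECT/RBR-specific, catalytically inactive and SUMO-specific E2s are
#' excluded, and (by default) RBR-class E3s.
#'
#' @param excluded_e2s E2 gene names to drop
#' @param exclude_rbr drop rows whose E3 is RBR-class
#' @return an `exclusion_policy` list
#' @export
exclusion_policy <- function(excluded_e2s = c("UBE2L3", "UBE2L6", "UBE2L5",
                                              "UBE2V1", "UBE2V2", "UBE2I"),
                             exclude_rbr = TRUE) {
  list(excluded_e2s = excluded_e2s, exclude_rbr = exclude_rbr)
}

#' Apply the exclusion policy to a labelled dataset
#'
#' @param dataset data.frame with `e2` and `e3` columns
#' @param policy an [exclusion_policy()]
#' @param e3_classes named character vector, E3 gene -> class
#' @return the filtered dataset, with attribute `removed` recording counts
#' @export
apply_exclusions <- function(dataset, policy, e3_classes) {
  missing_e3 <- setdiff(unique(dataset$e3), names(e3_classes))
  if (length(missing_e3)) {
    stop("missing E3 class annotation for: ", paste(missing_e3, collapse = ", "))
  }
  drop_e2 <- dataset$e2 %in% policy$excluded_e2s
  drop_rbr <- if (policy$exclude_rbr) {
    e3_classes[dataset$e3] == "RBR"
  } else rep(FALSE, nrow(dataset))
  out <- dataset[!(drop_e2 | drop_rbr), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(excluded_e2 = sum(drop_e2),
                            rbr_e3 = sum(drop_rbr & !drop_e2))
  out
}

#' Read a STRING-style physical-interaction edge table
#' @param path TSV with columns protein_a, protein_b, experimental_score and
#'   optionally combined_score
#' @return data.frame
#' @export
read_edge_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "experimental_score")
  if (!all(need %in% names(df))) {
    stop("edge table must have columns: ", paste(need, collapse = ", "))
  }
  df
}
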