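# Chain-role assignment by sequence identity and grouping of chains into
# ternary-complex copies.

.ROLES <- c("UBIQUITIN", "E2", "E3", "OTHER")

# Local pairwise alignment identity between two one-letter sequences.
# Returns identity over aligned (non-gap) columns and the aligned length.
seq_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(list(identity = 0, n_aligned = 0L))
  letters26 <- c(LETTERS)
  sm <- matrix(-1L, 26, 26, dimnames = list(letters26, letters26))
  diag(sm) <- 2L
  sm["X", "X"] <- -1L   # unknown residues never count as matches
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = sm,
    gapOpening = 10, gapExtension = 4
  )
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  n <- nm + nmm
  list(identity = if (n > 0) nm / n else 0, n_aligned = n)
}

# Best ungapped 76-residue window of `seq` against the ubiquitin reference;
# returns 1-based start index and identity.
.best_ub_window <- function(seq, ub_seq) {
  n <- nchar(seq); L <- nchar(ub_seq)
  if (n < L) return(list(start = 1L, identity = 0))
  ub <- strsplit(ub_seq, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  best <- list(start = 1L, identity = -1)
  for (i in seq_len(n - L + 1L)) {
    id <- mean(s[i:(i + L - 1L)] == ub)
    if (id > best$identity) best <- list(start = i, identity = id)
  }
  best
}

#' Assign ubiquitin / E2 / E3 roles to chains
#'
#' Each chain is matched against the reference registry by local-alignment
#' sequence identity: UBIQUITIN when >= 90% identical to ubiquitin over >= 70
#' aligned residues; otherwise E2 when the best E2-registry identity is
#' >= 60%; otherwise E3 when the best E3-registry identity is >= 60%;
#' otherwise OTHER. Explicit `overrides` win. Ubiquitin chains longer than 76
#' residues (fusions) are mapped to their best 76-residue window for all
#' downstream residue indexing.
#'
#' @param complex a `ternary_complex`
#' @param refs registry from [read_registry()]
#' @param overrides optional named character vector, chain id -> role
#'   (values among UBIQUITIN, E2, E3, OTHER; "UB" accepted for UBIQUITIN)
#' @return the complex with `$roles`, `$role_info` and `$ub_windows` filled
#' @export
assign_roles <- function(complex, refs, overrides = NULL) {
  chains <- unique(complex$atoms$chain[!complex$atoms$het])
  info <- data.frame(chain = chains, role = "OTHER", evidence = "no match",
                     identity = NA_real_, ref_gene = NA_character_,
                     stringsAsFactors = FALSE)
  for (k in seq_along(chains)) {
    ch <- chains[k]
    if (!is.null(overrides) && ch %in% names(overrides)) {
      role <- toupper(overrides[[ch]])
      if (role == "UB") role <- "UBIQUITIN"
      if (!role %in% .ROLES) stop("invalid override role: ", role)
      info$role[k] <- role; info$evidence[k] <- "override"
      next
    }
    seq <- chain_sequence(complex, ch)
    ub <- seq_identity(seq, refs$ubiquitin_seq)
    if (ub$identity >= 0.90 && ub$n_aligned >= 70) {
      info$role[k] <- "UBIQUITIN"
      info$evidence[k] <- sprintf("ubiquitin identity %.3f over %d residues",
                                  ub$identity, ub$n_aligned)
      info$identity[k] <- ub$identity
      next
    }
    best <- function(reg) {
      if (nrow(reg) == 0) return(list(identity = 0, gene = NA_character_))
      # identity counts only alignments covering >= half the registry entry,
      # so short coincidental local matches cannot claim a role
      ids <- vapply(reg$sequence, function(s) {
        si <- seq_identity(seq, s)
        if (si$n_aligned >= 0.5 * nchar(s)) si$identity else 0
      }, 0)
      i <- which.max(ids)
      list(identity = ids[i], gene = reg$gene[i])
    }
    b2 <- best(refs$e2)
    if (b2$identity >= 0.60) {
      info$role[k] <- "E2"; info$identity[k] <- b2$identity
      info$ref_gene[k] <- b2$gene
      info$evidence[k] <- sprintf("E2 registry %s identity %.3f", b2$gene, b2$identity)
      next
    }
    b3 <- best(refs$e3)
    if (b3$identity >= 0.60) {
      info$role[k] <- "E3"; info$identity[k] <- b3$identity
      info$ref_gene[k] <- b3$gene
      info$evidence[k] <- sprintf("E3 registry %s identity %.3f", b3$gene, b3$identity)
    }
  }
  complex$roles <- stats::setNames(info$role, info$chain)
  complex$role_info <- info
  # canonical-position map for ubiquitin chains (fusion-aware)
  complex$ub_windows <- list()
  for (ch in info$chain[info$role == "UBIQUITIN"]) {
    rt <- residue_table(complex, ch)
    seq <- paste0(aa3to1(rt$resname), collapse = "")
    if (nrow(rt) > 76) {
      w <- .best_ub_window(seq, refs$ubiquitin_seq)
      map <- rt$resno[w$start:(w$start + 75L)]
      complex$role_info$evidence[complex$role_info$chain == ch] <-
        paste0(info$evidence[info$chain == ch],
               sprintf("; fusion: truncated to window %d-%d",
                       map[1], map[76]))
    } else {
      # assume author numbering is canonical ubiquitin numbering
      map <- ifelse(1:76 %in% rt$resno, 1:76, NA_integer_)
    }
    complex$ub_windows[[ch]] <- stats::setNames(as.integer(map), 1:76)
  }
  complex
}

# Author residue number of canonical ubiquitin position `pos` on chain `ch`.
ub_resno <- function(complex, ch, pos) {
  w <- complex$ub_windows[[ch]]
  if (is.null(w)) return(pos)
  unname(w[as.character(pos)])
}

.chain_centroid <- function(complex, ch) {
  ca <- ca_matrix(complex, ch)
  ca <- ca[stats::complete.cases(ca), , drop = FALSE]
  if (nrow(ca) == 0) return(c(NA_real_, NA_real_, NA_real_))
  colMeans(ca)
}

#' Group chains into ternary-complex copies
#'
#' Pairs each ubiquitin chain with its nearest unused E2 chain by centroid
#' distance (ascending-distance greedy matching), then attaches the nearest
#' unused E3 chain (if any within range). Ubiquitin chains with no E2 within
#' 60 A are dropped with a warning.
#'
#' @param complex a `ternary_complex` with roles assigned
#' @param max_dist centroid-distance cutoff in Angstrom (default 60)
#' @return the complex with `$copies`: list of `list(ub, e2, e3)` (e3 may be
#'   `NA` for binary complexes)
#' @export
enumerate_copies <- function(complex, max_dist = 60) {
  if (is.null(complex$roles)) stop("roles must be assigned first")
  roles <- complex$roles
  ubs <- names(roles)[roles == "UBIQUITIN"]
  e2s <- names(roles)[roles == "E2"]
  e3s <- names(roles)[roles == "E3"]
  cent <- lapply(stats::setNames(nm = c(ubs, e2s, e3s)),
                 function(ch) .chain_centroid(complex, ch))
  pairs <- expand.grid(ub = ubs, e2 = e2s, stringsAsFactors = FALSE)
  if (nrow(pairs) > 0) {
    pairs$d <- mapply(function(u, e) sqrt(sum((cent[[u]] - cent[[e]])^2)),
                      pairs$ub, pairs$e2)
    pairs <- pairs[order(pairs$d, pairs$ub, pairs$e2), , drop = FALSE]
  }
  used_ub <- character(); used_e2 <- character(); copies <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    if (p$ub %in% used_ub || p$e2 %in% used_e2 || p$d > max_dist) next
    tie <- pairs[!(pairs$ub %in% used_ub) & !(pairs$e2 %in% used_e2) &
                   pairs$ub == p$ub & abs(pairs$d - p$d) < 1e-9, , drop = FALSE]
    if (length(unique(tie$e2)) > 1) {
      stop("ambiguous E2 assignment for ubiquitin chain ", p$ub,
           ": candidates ", paste(unique(tie$e2), collapse = ", "))
    }
    used_ub <- c(used_ub, p$ub); used_e2 <- c(used_e2, p$e2)
    copies[[length(copies) + 1L]] <- list(ub = p$ub, e2 = p$e2, e3 = NA_character_)
  }
  orphans <- setdiff(ubs, used_ub)
  if (length(orphans)) {
    warning("ubiquitin chain(s) with no E2 within ", max_dist, " A: ",
            paste(orphans, collapse = ", "), " (excluded from copies)")
  }
  used_e3 <- character()
  for (k in seq_along(copies)) {
    avail <- setdiff(e3s, used_e3)
    if (!length(avail)) next
    d3 <- vapply(avail, function(ch)
      sqrt(sum((cent[[copies[[k]]$e2]] - cent[[ch]])^2)), 0)
    j <- which.min(d3)
    if (d3[j] <= max_dist) {
      copies[[k]]$e3 <- avail[j]
      used_e3 <- c(used_e3, avail[j])
    }
  }
  complex$copies <- copies
  complex
}
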