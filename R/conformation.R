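# Closed/Open conformation classification from two diagnostic distances:
# ubiquitin Ile44 Calpha to the nearest E2 crossover-helix Calpha, and the
# ubiquitin residue-76 carbonyl carbon to the E2 catalytic-cysteine Calpha.

#' Cutoff parameters for conformation classification
#'
#' @param d_ile44 Ile44-to-helix cutoff in Angstrom (default 10)
#' @param d_tail ubiquitin-tail-to-cysteine cutoff in Angstrom (default 12)
#' @param apply_tail_criterion whether the tail criterion is applied; TRUE for
#'   predicted structures (no thioester bond anchors the tail), FALSE for
#'   experimental ones
#' @return a `cutoff_params` list
#' @export
cutoff_params <- function(d_ile44 = .ILE44_CUTOFF, d_tail = .TAIL_CUTOFF,
                          apply_tail_criterion = TRUE) {
  stopifnot(d_ile44 > 0, d_tail > 0)
  structure(list(d_ile44 = d_ile44, d_tail = d_tail,
                 apply_tail_criterion = apply_tail_criterion),
            class = "cutoff_params")
}

#' Minimum Ile44-to-crossover-helix distance for one copy
#'
#' Minimum Euclidean distance between the Calpha of ubiquitin residue 44 and
#' the Calpha atoms of the E2 crossover-helix residues.
#'
#' @param complex a `ternary_complex` with roles assigned
#' @param copy one element of `complex$copies`
#' @param helix crossover helix from [find_crossover_helix()]
#' @return distance in Angstrom
#' @export
ile44_helix_distance <- function(complex, copy, helix) {
  r44 <- ub_resno(complex, copy$ub, 44L)
  a44 <- atom_coords(complex, copy$ub, "CA", r44)
  if (is.na(r44) || nrow(a44$xyz) == 0) {
    stop("ubiquitin residue 44 Calpha missing on chain ", copy$ub)
  }
  hres <- seq.int(helix$start, helix$end)
  hca <- atom_coords(complex, copy$e2, "CA", hres)
  if (nrow(hca$xyz) == 0) stop("no resolved helix Calpha atoms on chain ", copy$e2)
  min(cross_dist(a44$xyz[1, , drop = FALSE], hca$xyz))
}

#' Ubiquitin-tail to catalytic-cysteine distance for one copy
#'
#' Distance from the carbonyl carbon of ubiquitin residue 76 (or, when 76 is
#' unresolved, the C-terminal-most resolved tail residue, flagged) to the
#' Calpha of the E2 catalytic cysteine.
#'
#' @inheritParams ile44_helix_distance
#' @param cys_resno author residue number of the catalytic cysteine, or `NA`
#'   for E2s that lack one (the UBE2V family); then the value is absent
#' @return list with `dist` (Angstrom or `NA`), `tail_resno` used, `flagged`
#'   (TRUE when a fallback tail residue was used)
#' @export
tail_cys_distance <- function(complex, copy, cys_resno) {
  if (is.null(cys_resno) || is.na(cys_resno)) {
    return(list(dist = NA_real_, tail_resno = NA_integer_, flagged = FALSE))
  }
  cys <- atom_coords(complex, copy$e2, "CA", cys_resno)
  if (nrow(cys$xyz) == 0) stop("catalytic cysteine Calpha missing on chain ", copy$e2)
  flagged <- FALSE
  tail_resno <- NA_integer_
  cpos <- NULL
  for (pos in 76:71) {
    rn <- ub_resno(complex, copy$ub, pos)
    if (is.na(rn)) next
    a <- atom_coords(complex, copy$ub, "C", rn)
    if (nrow(a$xyz) > 0) {
      cpos <- a$xyz[1, ]; tail_resno <- rn; flagged <- pos != 76L
      break
    }
  }
  if (is.null(cpos)) stop("no resolved ubiquitin tail carbonyl carbon on chain ", copy$ub)
  list(dist = sqrt(sum((cpos - cys$xyz[1, ])^2)),
       tail_resno = tail_resno, flagged = flagged)
}

#' Classify a ternary complex as Closed or Open
#'
#' Computes the two diagnostic distances for every copy in the asymmetric
#' unit, averages them across copies, and applies strict-inequality cutoffs:
#' Closed iff the averaged Ile44-helix distance is `< d_ile44` and (when the
#' tail criterion applies and is defined) the averaged tail-cysteine distance
#' is `< d_tail`. Complexes whose E2 lacks a catalytic cysteine are labelled
#' Open whenever the tail criterion applies. Boundary-equal distances are
#' Open.
#'
#' @param complex a `ternary_complex` with roles and copies assigned
#' @param registry_entry optional list/row with `helix_start`, `helix_end`,
#'   `catalytic_cys` (curated annotations for the E2)
#' @param params a [cutoff_params()] object
#' @return list: `ile44_helix_dist`, `tail_cys_dist` (copy-averaged, A),
#'   `label` ("Closed"/"Open"), `cutoffs`, `n_copies_averaged`, `tail_flagged`
#' @export
classify_conformation <- function(complex, registry_entry = NULL,
                                  params = cutoff_params()) {
  if (is.null(complex$copies) || length(complex$copies) == 0) {
    stop("no copies to classify; run enumerate_copies() first")
  }
  curated <- NULL; cys <- NA_integer_
  if (!is.null(registry_entry)) {
    hs <- registry_entry$helix_start; he <- registry_entry$helix_end
    if (!is.null(hs) && !is.na(hs)) curated <- c(hs, he)
    cc <- registry_entry$catalytic_cys
    if (!is.null(cc)) cys <- cc
  }
  d44 <- c(); dtail <- c(); flagged <- FALSE; n <- 0L
  for (copy in complex$copies) {
    helix <- find_crossover_helix(complex, copy$e2, curated = curated,
                                  cys_resno = if (is.na(cys)) NULL else cys)
    d44 <- c(d44, ile44_helix_distance(complex, copy, helix))
    tc <- tail_cys_distance(complex, copy, cys)
    dtail <- c(dtail, tc$dist)
    flagged <- flagged || tc$flagged
    n <- n + 1L
  }
  if (n == 0L) stop("no computable copy")
  m44 <- mean(d44)
  mtail <- if (all(is.na(dtail))) NA_real_ else mean(dtail, na.rm = TRUE)
  closed <- m44 < params$d_ile44
  if (params$apply_tail_criterion) {
    # no catalytic cysteine (UBE2V family) => Open in predicted mode
    closed <- closed && !is.na(mtail) && mtail < params$d_tail
  }
  list(ile44_helix_dist = m44, tail_cys_dist = mtail,
       label = if (closed) "Closed" else "Open",
       cutoffs = c(d_ile44 = params$d_ile44, d_tail = params$d_tail),
       n_copies_averaged = n, tail_flagged = flagged)
}

#' Closed/Open census over a set of structure files
#'
#' Convenience wrapper: loads each structure, assigns roles against the
#' registry, enumerates copies and classifies the conformation.
#'
#' @param paths structure file paths
#' @param refs registry from [read_registry()]
#' @param mode `"experimental"` (Ile44 criterion only) or `"predicted"`
#'   (both criteria)
#' @param params optional [cutoff_params()]; derived from `mode` when NULL
#' @return data.frame: complex_id, ile44_dist, tail_dist, label, n_copies
#' @export
conformation_census <- function(paths, refs,
                                mode = c("experimental", "predicted"),
                                params = NULL) {
  mode <- match.arg(mode)
  if (is.null(params)) {
    params <- cutoff_params(apply_tail_criterion = mode == "predicted")
  }
  rows <- lapply(paths, function(p) {
    cx <- load_structure(p, source = mode)
    cx <- assign_roles(cx, refs)
    cx <- enumerate_copies(cx)
    e2_chain <- cx$copies[[1]]$e2
    gene <- cx$role_info$ref_gene[cx$role_info$chain == e2_chain]
    reg <- refs$e2[match(gene, refs$e2$gene), , drop = FALSE]
    entry <- if (nrow(reg) == 1 && !is.na(gene)) as.list(reg) else NULL
    call <- classify_conformation(cx, registry_entry = entry, params = params)
    data.frame(complex_id = cx$complex_id,
               ile44_dist = call$ile44_helix_dist,
               tail_dist = call$tail_cys_dist,
               label = call$label,
               n_copies = call$n_copies_averaged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
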