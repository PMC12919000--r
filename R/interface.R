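# Interface residues, hydrogen bonds, linchpin calls, E3-loop engagement and
# interface RMSD.

.IFACE_NAMES <- c("UB-E2", "UB-E3", "E2-E3")

.iface_chains <- function(copy, pair) {
  switch(pair,
    "UB-E2" = c(copy$ub, copy$e2),
    "UB-E3" = c(copy$ub, copy$e3),
    "E2-E3" = c(copy$e2, copy$e3),
    stop("unknown interface name: ", pair, " (use UB-E2, UB-E3 or E2-E3)")
  )
}

#' Interface residues of a chain pair
#'
#' Residues (from both chains) whose Calpha lies within `cutoff` of some
#' Calpha of the partner chain. Symmetric; the empty set is valid.
#'
#' @param complex a `ternary_complex`
#' @param copy one element of `complex$copies`
#' @param pair interface name: `"UB-E2"`, `"UB-E3"` or `"E2-E3"`
#' @param cutoff Calpha-Calpha cutoff in Angstrom (default 8)
#' @return data.frame with columns `chain`, `resno`
#' @export
interface_residues <- function(complex, copy, pair, cutoff = .INTERFACE_CUTOFF) {
  ch <- .iface_chains(copy, pair)
  if (any(is.na(ch))) stop("interface ", pair, " not present in this copy")
  a <- atom_coords(complex, ch[1], "CA")
  b <- atom_coords(complex, ch[2], "CA")
  if (nrow(a$xyz) == 0 || nrow(b$xyz) == 0) stop("missing Calpha coordinates")
  d <- cross_dist(a$xyz, b$xyz)
  ia <- which(apply(d, 1, min) < cutoff)
  ib <- which(apply(d, 2, min) < cutoff)
  out <- rbind(
    data.frame(chain = rep(ch[1], length(ia)), resno = a$resno[ia],
               stringsAsFactors = FALSE),
    data.frame(chain = rep(ch[2], length(ib)), resno = b$resno[ib],
               stringsAsFactors = FALSE)
  )
  out[!duplicated(out), , drop = FALSE]
}

#' Distance-based hydrogen-bond detection between two chains
#'
#' Every inter-chain pair of nitrogen/oxygen heavy atoms within `cutoff`
#' (default 3.5 A) is reported as one bond. Donor/acceptor chemistry is
#' simplified to element class (N and O can act as either); sulfur excluded.
#' No hydrogen positions or angle criteria are used.
#'
#' @param complex a `ternary_complex`
#' @param chain_a,chain_b chain ids
#' @param resno_a,resno_b optional residue-number restrictions
#' @param cutoff distance cutoff in Angstrom
#' @return data.frame: chain_a, resno_a, atom_a, chain_b, resno_b, atom_b, dist
#' @export
detect_hbonds <- function(complex, chain_a, chain_b, resno_a = NULL,
                          resno_b = NULL, cutoff = .HBOND_CUTOFF) {
  pol <- function(ch, rn) {
    at <- heavy_atoms(complex, ch, rn)
    at[at$element %in% c("N", "O"), , drop = FALSE]
  }
  a <- pol(chain_a, resno_a); b <- pol(chain_b, resno_b)
  empty <- data.frame(chain_a = character(), resno_a = integer(),
                      atom_a = character(), chain_b = character(),
                      resno_b = integer(), atom_b = character(),
                      dist = numeric(), stringsAsFactors = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  d <- cross_dist(as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(b[, c("x", "y", "z")]))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  out <- data.frame(
    chain_a = chain_a, resno_a = a$resno[hit[, 1]], atom_a = a$atom[hit[, 1]],
    chain_b = chain_b, resno_b = b$resno[hit[, 2]], atom_b = b$atom[hit[, 2]],
    dist = d[hit], stringsAsFactors = FALSE
  )
  out[order(out$resno_a, out$atom_a, out$resno_b, out$atom_b), , drop = FALSE]
}

#' E3 engagement of the E2 binding loop
#'
#' The E2-interaction region of the E3 comprises E3 residues with any heavy
#' atom within `cutoff` of any heavy atom of the E2 binding loop. Loop (coil)
#' segments of the E3 — neither helix nor strand by the Calpha-geometry
#' detector — intersecting that region are counted.
#'
#' @param complex a `ternary_complex`
#' @param copy a copy with an E3 chain
#' @param e2_loop integer `c(start, end)` span of the E2 binding loop
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 8)
#' @return list: `n_e3_loops`, `n_e3_loop_residues`, `region_resno`
#'   (E3 residues in the interaction region), `e2_binding_loop`
#' @export
e3_engagement <- function(complex, copy, e2_loop, cutoff = .INTERFACE_CUTOFF) {
  if (is.na(copy$e3)) stop("copy has no E3 chain")
  if (length(e2_loop) == 0) {
    return(list(n_e3_loops = 0L, n_e3_loop_residues = 0L,
                region_resno = integer(0), e2_binding_loop = e2_loop))
  }
  loop_at <- heavy_atoms(complex, copy$e2,
                         seq.int(e2_loop[1], e2_loop[2]))
  e3_at <- heavy_atoms(complex, copy$e3)
  if (nrow(loop_at) == 0 || nrow(e3_at) == 0) {
    return(list(n_e3_loops = 0L, n_e3_loop_residues = 0L,
                region_resno = integer(0), e2_binding_loop = e2_loop))
  }
  d <- cross_dist(as.matrix(e3_at[, c("x", "y", "z")]),
                  as.matrix(loop_at[, c("x", "y", "z")]))
  in_range <- apply(d, 1, min) <= cutoff
  region <- sort(unique(e3_at$resno[in_range]))
  ca <- ca_matrix(complex, copy$e3)
  resno <- as.integer(rownames(ca))
  fl <- ss_flags(ca)
  coil <- !(fl$helix | fl$strand)
  segs <- .runs(coil)
  n_loops <- 0L; n_res <- 0L
  for (k in seq_len(nrow(segs))) {
    seg_res <- resno[segs$start[k]:segs$end[k]]
    inter <- intersect(seg_res, region)
    if (length(inter)) {
      n_loops <- n_loops + 1L
      n_res <- n_res + length(inter)
    }
  }
  list(n_e3_loops = n_loops, n_e3_loop_residues = n_res,
       region_resno = region, e2_binding_loop = e2_loop)
}

#' Detect the linchpin residue of a ternary complex
#'
#' A linchpin is an E3 residue inside the E2-interaction region that forms
#' hydrogen bonds both with the ubiquitin C-terminal tail (canonical residues
#' 71-76, or the resolved subset) and with the E2. The structure-level call is
#' present iff at least half of the copies have one; the reported residue is
#' the most frequent across copies, ties broken by lowest residue number.
#'
#' @param complex a `ternary_complex` with roles and copies
#' @param helix_curated,cys_resno,loop_curated optional curated annotations
#'   for the E2 (helix span, catalytic cysteine, binding loop)
#' @return list: `present`, `residue` (list(chain, resno, resname) or NULL),
#'   `fraction_of_copies`, `per_copy` (list of per-copy linchpin resno sets)
#' @export
detect_linchpin <- function(complex, helix_curated = NULL, cys_resno = NULL,
                            loop_curated = NULL) {
  copies <- Filter(function(cp) !is.na(cp$e3), complex$copies)
  if (length(copies) == 0) {
    return(list(present = NA, residue = NULL, fraction_of_copies = NA_real_,
                per_copy = list()))
  }
  per_copy <- list()
  for (copy in copies) {
    helix <- find_crossover_helix(complex, copy$e2, curated = helix_curated,
                                  cys_resno = cys_resno)
    loop <- find_e2_binding_loop(complex, helix, curated = loop_curated)
    eng <- e3_engagement(complex, copy, loop)
    tail_resno <- stats::na.omit(vapply(71:76, function(p)
      ub_resno(complex, copy$ub, p), 0L))
    found <- integer(0)
    for (rn in eng$region_resno) {
      hb_tail <- detect_hbonds(complex, copy$e3, copy$ub,
                               resno_a = rn, resno_b = tail_resno)
      if (nrow(hb_tail) == 0) next
      hb_e2 <- detect_hbonds(complex, copy$e3, copy$e2, resno_a = rn)
      if (nrow(hb_e2) > 0) found <- c(found, rn)
    }
    per_copy[[length(per_copy) + 1L]] <- found
  }
  frac <- mean(vapply(per_copy, function(v) length(v) > 0, TRUE))
  present <- frac >= 0.5
  residue <- NULL
  if (present) {
    all_rn <- unlist(per_copy)
    tab <- table(all_rn)
    best <- as.integer(names(tab)[tab == max(tab)])
    rn <- min(best)
    ch3 <- copies[[1]]$e3
    rt <- residue_table(complex, ch3)
    residue <- list(chain = ch3, resno = rn,
                    resname = rt$resname[match(rn, rt$resno)])
  }
  list(present = present, residue = residue, fraction_of_copies = frac,
       per_copy = per_copy)
}

# Canonical (role, position) labels for interface residues of one copy;
# ubiquitin residues are mapped to canonical 1-76 positions.
.canon_iface <- function(complex, copy, pair, cutoff) {
  ir <- interface_residues(complex, copy, pair, cutoff)
  role_of <- function(ch) {
    if (identical(ch, copy$ub)) "UB" else if (identical(ch, copy$e2)) "E2" else "E3"
  }
  pos <- integer(nrow(ir)); role <- character(nrow(ir))
  for (i in seq_len(nrow(ir))) {
    role[i] <- role_of(ir$chain[i])
    if (role[i] == "UB") {
      w <- complex$ub_windows[[ir$chain[i]]]
      pos[i] <- if (is.null(w)) ir$resno[i] else {
        m <- match(ir$resno[i], w)
        if (is.na(m)) NA_integer_ else m
      }
    } else pos[i] <- ir$resno[i]
  }
  keep <- !is.na(pos)
  data.frame(role = role[keep], pos = pos[keep], chain = ir$chain[keep],
             resno = ir$resno[keep], stringsAsFactors = FALSE)
}

#' Interface RMSD between a reference and a model complex
#'
#' Superposes the model onto the reference with a Kabsch fit computed from
#' paired crossover-helix Calpha atoms only (paired by offset from the helix
#' start), then computes Calpha RMSD over interface residues (8 A rule)
#' present in both structures, per interface and overall. Non-ternary chains
#' are ignored.
#'
#' @param reference,model `ternary_complex` objects with roles and copies
#' @param ref_helix,model_helix crossover helices ([find_crossover_helix()]);
#'   detected when NULL (requires detectable geometry)
#' @param cutoff interface Calpha cutoff in Angstrom
#' @return list: `per_interface` (named numeric, A), `overall` (A),
#'   `n_common_residues`
#' @export
interface_rmsd <- function(reference, model, ref_helix = NULL,
                           model_helix = NULL, cutoff = .INTERFACE_CUTOFF) {
  rcp <- reference$copies[[1]]; mcp <- model$copies[[1]]
  if (is.null(ref_helix)) ref_helix <- find_crossover_helix(reference, rcp$e2)
  if (is.null(model_helix)) model_helix <- find_crossover_helix(model, mcp$e2)
  n <- min(ref_helix$end - ref_helix$start, model_helix$end - model_helix$start) + 1L
  ref_res <- seq.int(ref_helix$start, length.out = n)
  mod_res <- seq.int(model_helix$start, length.out = n)
  rca <- atom_coords(reference, rcp$e2, "CA", ref_res)
  mca <- atom_coords(model, mcp$e2, "CA", mod_res)
  common <- intersect(match(ref_res, rca$resno), match(mod_res, mca$resno))
  ri <- match(ref_res, rca$resno); mi <- match(mod_res, mca$resno)
  ok <- !is.na(ri) & !is.na(mi)
  if (sum(ok) < 3) stop("insufficient anchor: fewer than 3 paired helix residues")
  rt <- kabsch(mca$xyz[mi[ok], , drop = FALSE], rca$xyz[ri[ok], , drop = FALSE])
  model_fit <- transform_complex(model, rt$R, rt$t)
  ifaces <- if (is.na(rcp$e3) || is.na(mcp$e3)) "UB-E2" else .IFACE_NAMES
  per <- stats::setNames(rep(NA_real_, length(ifaces)), ifaces)
  all_sq <- c()     # overall uses the union of common residues across interfaces
  seen <- character(0)
  n_common <- 0L
  chain_of <- function(cp, role) switch(role, UB = cp$ub, E2 = cp$e2, E3 = cp$e3)
  resno_of <- function(complex, cp, role, pos) {
    if (role == "UB") ub_resno(complex, chain_of(cp, role), pos) else pos
  }
  for (pair in ifaces) {
    a <- .canon_iface(reference, rcp, pair, cutoff)
    b <- .canon_iface(model_fit, mcp, pair, cutoff)
    key_a <- paste(a$role, a$pos); key_b <- paste(b$role, b$pos)
    shared <- intersect(key_a, key_b)
    if (!length(shared)) next
    sq <- numeric(0)
    for (k in shared) {
      role <- sub(" .*", "", k); pos <- as.integer(sub(".* ", "", k))
      pr <- atom_coords(reference, chain_of(rcp, role), "CA",
                        resno_of(reference, rcp, role, pos))
      pm <- atom_coords(model_fit, chain_of(mcp, role), "CA",
                        resno_of(model_fit, mcp, role, pos))
      if (nrow(pr$xyz) == 0 || nrow(pm$xyz) == 0) next
      dev2 <- sum((pr$xyz[1, ] - pm$xyz[1, ])^2)
      sq <- c(sq, dev2)
      if (!k %in% seen) {
        seen <- c(seen, k)
        all_sq <- c(all_sq, dev2)
      }
    }
    if (length(sq)) {
      per[pair] <- sqrt(mean(sq))
      n_common <- length(seen)
    }
  }
  list(per_interface = per,
       overall = if (length(all_sq)) sqrt(mean(all_sq)) else NA_real_,
       n_common_residues = n_common)
}
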