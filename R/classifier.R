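# Feature assembly, nested stratified cross-validation of the boosted-tree
# pair/non-pair classifier, F-beta threshold selection, final training and
# partner prediction.

.IFACE_TAGS <- c("UB-E2" = "ub_e2", "UB-E3" = "ub_e3", "E2-E3" = "e2_e3")
.CONF_FEATURES <- c("ipsae", "iptm", "pdockq", "pdockq2")
.ENER_FEATURES <- c("dG", "dSASA", "dSASA_polar", "dSASA_nonpolar",
                    "hbonds_total", "hbonds_unsat", "n_interface_residues")
.COMPLEX_FEATURES <- c("ile44_helix_dist", "tail_cys_dist", "linchpin_flag",
                       "n_e3_loops", "n_e3_loop_residues")

#' Names of the full model feature set
#'
#' Three interfaces x 11 per-interface features plus 5 complex-level features
#' (38 columns). Mean interface PAE is deliberately not a feature.
#'
#' @return character vector of 38 feature names
#' @export
feature_schema <- function() {
  per_iface <- c(.CONF_FEATURES, .ENER_FEATURES)
  c(as.vector(t(outer(unname(.IFACE_TAGS), per_iface, paste, sep = "_"))),
    .COMPLEX_FEATURES)
}

#' Assemble the labelled feature table
#'
#' Inner join of the three per-complex sources, keeping only complexes with
#' complete feature sets; rows whose conformation is not Closed are removed.
#'
#' @param structural data.frame, one row per complex: `complex_id`, `e2`,
#'   `e3`, optional `label`, `conformation` ("Closed"/"Open") and the
#'   complex-level features (`ile44_helix_dist`, `tail_cys_dist`,
#'   `linchpin_flag`, `n_e3_loops`, `n_e3_loop_residues`)
#' @param confidence long data.frame: `complex_id`, `interface` (UB-E2 etc.)
#'   and the per-interface confidence features (`ipsae`, `iptm`, `pdockq`,
#'   `pdockq2`)
#' @param energetics output of [parse_energetics()]
#' @param max_missing maximum tolerated missingness per feature column before
#'   an error (default 0.2)
#' @return data.frame: complex_id, e2, e3, label (if present) and the 38
#'   feature columns
#' @export
assemble_features <- function(structural, confidence, energetics,
                              max_missing = 0.2) {
  out <- structural
  for (ifc in names(.IFACE_TAGS)) {
    sub <- confidence[confidence$interface == ifc, , drop = FALSE]
    idx <- match(out$complex_id, sub$complex_id)
    for (m in .CONF_FEATURES) {
      out[[paste0(.IFACE_TAGS[[ifc]], "_", m)]] <- sub[[m]][idx]
    }
  }
  out <- merge_energetics(out, energetics)
  # contract column names -> schema names
  for (tag in .IFACE_TAGS) {
    names(out)[names(out) == paste0(tag, "_hbonds_int")] <-
      paste0(tag, "_hbonds_total")
    names(out)[names(out) == paste0(tag, "_nres")] <-
      paste0(tag, "_n_interface_residues")
  }
  if ("conformation" %in% names(out)) {
    out <- out[out$conformation == "Closed", , drop = FALSE]
  }
  feats <- feature_schema()
  missing_cols <- setdiff(feats, names(out))
  if (length(missing_cols)) {
    stop("feature columns absent from inputs: ",
         paste(missing_cols, collapse = ", "))
  }
  frac_na <- vapply(out[feats], function(v) mean(is.na(v)), 0)
  bad <- names(frac_na)[frac_na > max_missing]
  if (length(bad)) {
    stop("feature(s) exceed ", max_missing * 100, "% missingness: ",
         paste(bad, collapse = ", "))
  }
  complete <- stats::complete.cases(out[feats])
  out <- out[complete, , drop = FALSE]
  rownames(out) <- NULL
  keep <- c(intersect(c("complex_id", "e2", "e3", "label", "conformation"),
                      names(out)), feats)
  out[, keep, drop = FALSE]
}

#' Equalise pair / non-pair class counts
#'
#' Adds randomly selected rows from a candidate non-pair pool until the two
#' classes are equal in size. Deterministic given `seed`.
#'
#' @param table labelled feature table (column `label`: pair/nonpair)
#' @param candidate_nonpairs feature table of additional non-pair rows
#' @param seed integer seed
#' @return the balanced table (attribute `added` = rows added)
#' @export
balance_classes <- function(table, candidate_nonpairs, seed) {
  n_pair <- sum(table$label == "pair")
  n_non <- sum(table$label == "nonpair")
  deficit <- n_pair - n_non
  if (deficit <= 0) {
    attr(table, "added") <- 0L
    return(table)
  }
  pool <- candidate_nonpairs[!(candidate_nonpairs$complex_id %in%
                                 table$complex_id), , drop = FALSE]
  take <- min(deficit, nrow(pool))
  if (take < deficit) {
    message("candidate pool exhausted: achievable balance is ",
            n_pair, " vs ", n_non + take)
  }
  if (take > 0) {
    idx <- withr_seed_sample(nrow(pool), take, seed)
    add <- pool[idx, , drop = FALSE]
    add$label <- "nonpair"
    table <- rbind(table, add[, names(table), drop = FALSE])
  }
  rownames(table) <- NULL
  attr(table, "added") <- take
  table
}

#' Training configuration
#' @param n_outer_folds outer CV folds (default 5)
#' @param n_inner_folds inner CV folds (default 3)
#' @param stratified stratify folds by label (default TRUE)
#' @param beta F-beta weight used for threshold choice (default 0.75)
#' @param seed integer seed for fold assignment
#' @param feature_selection `"importance_threshold"` (keep features with
#'   importance >= mean importance of a preliminary fit) or `"none"`
#' @param balance whether class balancing was applied upstream (recorded)
#' @param grid data.frame of hyperparameter candidates (max_depth, eta,
#'   nrounds) searched in the inner loop
#' @return a `training_config` list
#' @export
training_config <- function(n_outer_folds = 5L, n_inner_folds = 3L,
                            stratified = TRUE, beta = 0.75, seed = 1L,
                            feature_selection = c("importance_threshold", "none"),
                            balance = TRUE,
                            grid = expand.grid(max_depth = c(2L, 3L),
                                               eta = c(0.1, 0.3),
                                               nrounds = 100L)) {
  stopifnot(n_outer_folds >= 2, n_inner_folds >= 2, beta > 0)
  list(n_outer_folds = n_outer_folds, n_inner_folds = n_inner_folds,
       stratified = stratified, beta = beta, seed = as.integer(seed),
       feature_selection = match.arg(feature_selection), balance = balance,
       grid = grid)
}

# Stratified fold assignment; returns integer fold id per row.
make_folds <- function(y, k, seed, stratified = TRUE) {
  fold <- integer(length(y))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  } else {
    fold <- sample(rep(seq_len(k), length.out = length(y)))
  }
  fold
}

#' Area under the ROC curve (rank statistic)
#' @param probs predicted probabilities
#' @param labels 0/1 vector
#' @return AUC in `[0, 1]`
#' @export
roc_auc <- function(probs, labels) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

.fbeta <- function(precision, recall, beta) {
  if (is.na(precision) || is.na(recall) || precision + recall == 0) return(0)
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

.confusion <- function(probs, labels, threshold) {
  pred <- as.integer(probs >= threshold)
  c(tp = sum(pred == 1 & labels == 1), fp = sum(pred == 1 & labels == 0),
    fn = sum(pred == 0 & labels == 1), tn = sum(pred == 0 & labels == 0))
}

#' Select a decision threshold by maximising the F-beta score
#'
#' Scans all unique predicted probabilities as candidate thresholds
#' (prediction positive when `prob >= threshold`); ties are broken by the
#' lower threshold.
#'
#' @param probs out-of-fold probabilities
#' @param labels 0/1 vector
#' @param beta recall weight (default 0.75; < 1 favours precision)
#' @return threshold in `[0, 1]`
#' @export
choose_threshold <- function(probs, labels, beta = 0.75) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("undefined threshold: labels contain a single class")
  }
  cand <- sort(unique(probs))
  best_t <- cand[1]; best_f <- -Inf
  for (t in cand) {
    cm <- .confusion(probs, labels, t)
    prec <- if (cm["tp"] + cm["fp"] > 0) cm["tp"] / (cm["tp"] + cm["fp"]) else NA
    rec <- cm["tp"] / (cm["tp"] + cm["fn"])
    f <- .fbeta(prec, rec, beta)
    if (f > best_f + 1e-12) { best_f <- f; best_t <- t }
  }
  unname(best_t)
}

# Importance-threshold feature selection on a preliminary fit. The prelim fit
# uses aggressive column subsampling so that gain spreads over every
# informative feature rather than piling onto one dominant column; the
# selection rule itself stays "importance >= mean importance".
.select_features <- function(x, y, hp, mode) {
  if (mode == "none") return(colnames(x))
  prelim <- gbt_fit(x, y, nrounds = hp$nrounds, eta = hp$eta,
                    max_depth = hp$max_depth, colsample_bytree = 0.3)
  imp <- prelim$importance
  keep <- names(imp)[imp >= mean(imp)]
  if (!length(keep)) colnames(x) else keep
}

#' Nested stratified cross-validation of the pair classifier
#'
#' Outer folds are stratified by label. Inside each outer training set, the
#' hyperparameter grid is scored by inner-fold CV with feature selection
#' performed on each inner training set only (no information from outer test
#' folds leaks into selection or tuning). The best configuration is refitted
#' on the outer training set and scored on the outer test fold.
#'
#' @param table feature table from [assemble_features()] with a `label` column
#' @param config a [training_config()]
#' @return a `cv_report`: per-fold and mean accuracy/precision/recall/AUC,
#'   out-of-fold probabilities, chosen threshold, confusion matrix at that
#'   threshold, selected features and hyperparameters per fold
#' @export
nested_cv <- function(table, config = training_config()) {
  feats <- intersect(feature_schema(), names(table))
  x <- as.matrix(table[, feats, drop = FALSE])
  y <- as.integer(table$label == "pair")
  if (min(table(y)) < 10) stop("need >= 10 rows per class")
  outer <- make_folds(y, config$n_outer_folds, config$seed, config$stratified)
  oof <- rep(NA_real_, length(y))
  fold_rows <- list(); sel_feats <- list(); sel_hp <- list()
  for (f in seq_len(config$n_outer_folds)) {
    tr <- which(outer != f); te <- which(outer == f)
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
      stop("stratification error: a fold lacks one class")
    }
    inner <- make_folds(y[tr], config$n_inner_folds,
                        config$seed + 1000L + f, config$stratified)
    grid_auc <- numeric(nrow(config$grid))
    for (g in seq_len(nrow(config$grid))) {
      hp <- config$grid[g, ]
      aucs <- numeric(config$n_inner_folds)
      for (i in seq_len(config$n_inner_folds)) {
        itr <- tr[inner != i]; ite <- tr[inner == i]
        keep <- .select_features(x[itr, , drop = FALSE], y[itr], hp,
                                 config$feature_selection)
        fit <- gbt_fit(x[itr, keep, drop = FALSE], y[itr],
                       nrounds = hp$nrounds, eta = hp$eta,
                       max_depth = hp$max_depth)
        p <- predict(fit, x[ite, keep, drop = FALSE])
        aucs[i] <- roc_auc(p, y[ite])
      }
      grid_auc[g] <- mean(aucs, na.rm = TRUE)
    }
    best <- which.max(grid_auc)
    hp <- config$grid[best, ]
    keep <- .select_features(x[tr, , drop = FALSE], y[tr], hp,
                             config$feature_selection)
    fit <- gbt_fit(x[tr, keep, drop = FALSE], y[tr], nrounds = hp$nrounds,
                   eta = hp$eta, max_depth = hp$max_depth)
    oof[te] <- predict(fit, x[te, keep, drop = FALSE])
    fold_rows[[f]] <- te; sel_feats[[f]] <- keep; sel_hp[[f]] <- hp
  }
  threshold <- choose_threshold(oof, y, config$beta)
  per_fold <- do.call(rbind, lapply(seq_len(config$n_outer_folds), function(f) {
    te <- fold_rows[[f]]
    cm <- .confusion(oof[te], y[te], threshold)
    data.frame(
      fold = f,
      accuracy = (cm["tp"] + cm["tn"]) / length(te),
      precision = if (cm["tp"] + cm["fp"] > 0) cm["tp"] / (cm["tp"] + cm["fp"]) else NA_real_,
      recall = cm["tp"] / (cm["tp"] + cm["fn"]),
      roc_auc = roc_auc(oof[te], y[te]),
      row.names = NULL
    )
  }))
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[, -1], na.rm = TRUE),
    oof_probabilities = oof,
    labels = y,
    threshold = threshold,
    confusion = .confusion(oof, y, threshold),
    selected_features = sel_feats,
    hyperparameters = sel_hp,
    config = config
  ), class = "cv_report")
}

#' Train the final classifier on the full table
#'
#' Fits the boosted-tree model on all rows using importance-threshold feature
#' selection, and stores the decision threshold (typically the one chosen
#' from nested-CV out-of-fold probabilities).
#'
#' @param table labelled feature table
#' @param config a [training_config()]
#' @param threshold decision threshold; when NULL, [nested_cv()] is run and
#'   its threshold used
#' @param hyperparameters optional list/row with max_depth, eta, nrounds;
#'   defaults to the first grid row
#' @return a `pair_classifier`: gbt model, features, threshold, config
#' @export
train_final <- function(table, config = training_config(), threshold = NULL,
                        hyperparameters = NULL) {
  feats <- intersect(feature_schema(), names(table))
  x <- as.matrix(table[, feats, drop = FALSE])
  y <- as.integer(table$label == "pair")
  if (is.null(threshold)) {
    threshold <- nested_cv(table, config)$threshold
  }
  hp <- hyperparameters %||% config$grid[1, ]
  keep <- .select_features(x, y, hp, config$feature_selection)
  fit <- gbt_fit(x[, keep, drop = FALSE], y, nrounds = hp$nrounds,
                 eta = hp$eta, max_depth = hp$max_depth)
  structure(list(model = fit, features = keep, threshold = threshold,
                 beta = config$beta, seed = config$seed,
                 hyperparameters = as.list(hp)),
            class = "pair_classifier")
}

#' Persist / reload a trained pair classifier
#'
#' The model is written as JSON (trees, feature list, threshold, seed and
#' hyperparameters) plus a small manifest; text only.
#'
#' @param model a `pair_classifier`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
save_classifier <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(gbt = gbt_to_list(model$model), features = model$features,
         threshold = model$threshold, beta = model$beta, seed = model$seed,
         hyperparameters = model$hyperparameters),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = "ubiqpair", n_features = length(model$features),
         threshold = model$threshold, seed = model$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  lst <- jsonlite::read_json(file.path(dir, "model.json"),
                             simplifyVector = FALSE)
  structure(list(model = gbt_from_list(lst$gbt),
                 features = unlist(lst$features),
                 threshold = lst$threshold, beta = lst$beta, seed = lst$seed,
                 hyperparameters = lst$hyperparameters),
            class = "pair_classifier")
}

#' Prediction prefilter
#' @param require_closed drop candidates not in the Closed conformation
#' @param require_ring_engagement drop candidates whose E2 does not engage the
#'   E3 RING/U-box domain (>= 1 E2-E3 interface residue pair with the E3
#'   residue inside the RING/U-box truncation span)
#' @param min_ptm,min_iptm minimum global pTM / ipTM
#' @return a `prediction_prefilter` list
#' @export
prediction_prefilter <- function(require_closed = TRUE,
                                 require_ring_engagement = TRUE,
                                 min_ptm = 0.5, min_iptm = 0.5) {
  list(require_closed = require_closed,
       require_ring_engagement = require_ring_engagement,
       min_ptm = min_ptm, min_iptm = min_iptm)
}

#' Predict E2 partners for candidate E2-E3 complexes
#'
#' Applies the prefilter, scores the survivors with the trained classifier,
#' thresholds into predicted pairs, and summarises per E3 — flagging E3s with
#' exactly one predicted E2 partner as uniquely predicted.
#'
#' @param model a `pair_classifier`
#' @param candidates feature table with additionally `e2`, `e3`,
#'   `conformation`, `ring_engagement` (logical/0-1), `ptm`, `iptm`
#' @param prefilter a [prediction_prefilter()]
#' @return list: `predictions` (scored rows), `per_e3` (n_predicted,
#'   unique flag, predicted E2s), `filtered` (reason counts)
#' @export
predict_partners <- function(model, candidates,
                             prefilter = prediction_prefilter()) {
  reasons <- c(open = 0L, no_ring_engagement = 0L, low_ptm = 0L,
               low_iptm = 0L)
  keep <- rep(TRUE, nrow(candidates))
  if (prefilter$require_closed) {
    bad <- candidates$conformation != "Closed"
    reasons["open"] <- sum(bad); keep <- keep & !bad
  }
  if (prefilter$require_ring_engagement) {
    bad <- !(as.logical(candidates$ring_engagement))
    reasons["no_ring_engagement"] <- sum(bad & keep); keep <- keep & !bad
  }
  bad <- candidates$ptm < prefilter$min_ptm
  reasons["low_ptm"] <- sum(bad & keep); keep <- keep & !bad
  bad <- candidates$iptm < prefilter$min_iptm
  reasons["low_iptm"] <- sum(bad & keep); keep <- keep & !bad
  surv <- candidates[keep, , drop = FALSE]
  if (nrow(surv) == 0) {
    return(list(predictions = data.frame(), per_e3 = data.frame(),
                filtered = reasons))
  }
  probs <- predict(model$model,
                   as.matrix(surv[, model$features, drop = FALSE]))
  surv$probability <- probs
  surv$predicted_pair <- probs >= model$threshold
  agg <- lapply(split(surv, surv$e3), function(d) {
    e2s <- d$e2[d$predicted_pair]
    data.frame(e3 = d$e3[1], n_predicted = length(e2s),
               unique_prediction = length(e2s) == 1L,
               predicted_e2s = paste(sort(e2s), collapse = ","),
               stringsAsFactors = FALSE)
  })
  per_e3 <- do.call(rbind, agg)
  rownames(per_e3) <- NULL
  list(predictions = surv, per_e3 = per_e3, filtered = reasons)
}
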