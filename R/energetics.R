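# Ingest of per-interface energetics tables produced by an external
# interface-analysis tool. The tool itself is never invoked; a TSV contract
# decouples it (columns: complex_id, interface, dG, dSASA, dSASA_polar,
# dSASA_nonpolar, hbonds_int, hbonds_unsat, nres).

.ENERGETICS_COLS <- c("complex_id", "interface", "dG", "dSASA", "dSASA_polar",
                      "dSASA_nonpolar", "hbonds_int", "hbonds_unsat", "nres")

#' Parse a per-interface energetics TSV
#'
#' Expects one row per (complex, interface); three interfaces per complex.
#' Complexes with fewer than three rows are flagged, not dropped.
#'
#' @param path TSV file
#' @param dialect free-text tag recorded on the result (tool provenance)
#' @return data.frame with the contract columns plus a `partial` flag;
#'   attribute `dialect`
#' @export
parse_energetics <- function(path, dialect = "interface-analyzer") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.ENERGETICS_COLS, names(df))
  if (length(miss)) stop("energetics table missing columns: ",
                         paste(miss, collapse = ", "))
  key <- paste(df$complex_id, df$interface)
  if (anyDuplicated(key)) {
    stop("duplicate (complex, interface) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  bad <- df$dSASA_polar > df$dSASA + 1e-3 | df$dSASA_nonpolar > df$dSASA + 1e-3
  if (any(bad)) stop("SASA components exceed total for ",
                     paste(df$complex_id[bad], collapse = ", "))
  counts <- table(df$complex_id)
  df$partial <- unname(counts[df$complex_id] < 3L)
  attr(df, "dialect") <- dialect
  df
}

#' Merge energetics into a feature table
#'
#' Left join on `(complex_id, interface)` for long tables, or on `complex_id`
#' after widening when the feature table is one row per complex. Unmatched
#' energetics rows are reported via a message; feature rows are never dropped
#' or duplicated.
#'
#' @param features data.frame keyed by `complex_id` (one row per complex);
#'   energetics columns are added per interface as
#'   `<iface>_<metric>` with iface in ub_e2, ub_e3, e2_e3
#' @param energetics output of [parse_energetics()]
#' @return the joined data.frame
#' @export
merge_energetics <- function(features, energetics) {
  iface_tag <- c("UB-E2" = "ub_e2", "UB-E3" = "ub_e3", "E2-E3" = "e2_e3")
  metrics <- c("dG", "dSASA", "dSASA_polar", "dSASA_nonpolar",
               "hbonds_int", "hbonds_unsat", "nres")
  out <- features
  for (ifc in names(iface_tag)) {
    sub <- energetics[energetics$interface == ifc, , drop = FALSE]
    idx <- match(out$complex_id, sub$complex_id)
    for (m in metrics) {
      col <- paste0(iface_tag[[ifc]], "_", m)
      vals <- sub[[m]][idx]
      if (!col %in% names(out) || all(is.na(out[[col]]))) {
        out[[col]] <- vals
      } else {
        out[[col]] <- ifelse(is.na(out[[col]]), vals, out[[col]])
      }
    }
  }
  unmatched <- setdiff(unique(energetics$complex_id), features$complex_id)
  if (length(unmatched)) {
    message("energetics rows with no matching feature complex: ",
            paste(unmatched, collapse = ", "))
  }
  out
}
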