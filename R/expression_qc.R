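#' Read a qPCR Ct table
#'
#' Expected CSV columns: `sample_id`, `phenotype` (coated/hairless),
#' `assay` (gene or primer-set id), `ct` (threshold cycle, positive), and
#' optionally `replicate`.
#'
#' @param path Path to the CSV file.
#' @return data.frame of Ct records.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "phenotype", "assay", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0))
    stop("ct values must be positive threshold cycles")
  df
}

#' Normalize target Ct against housekeeping assays (delta-Ct)
#'
#' Technical replicates are first combined by arithmetic mean of Ct per
#' (sample, assay). In `per_gene` mode one delta-Ct is emitted per
#' (sample, housekeeping assay): `Ct_target - Ct_housekeeping`. In `mean`
#' mode one delta-Ct per sample: `Ct_target - mean(Ct_housekeeping)`.
#' Higher delta-Ct means lower relative expression of the target.
#'
#' Samples lacking a target measurement or any required housekeeping
#' measurement are not silently dropped: they are reported in the
#' `skipped` attribute of the result.
#'
#' @param records data.frame of Ct records (see [read_ct_table()]).
#' @param target Target assay id (e.g. the candidate gene).
#' @param housekeeping Character vector of housekeeping assay ids.
#' @param reference_mode `"per_gene"` (default) or `"mean"`.
#' @return data.frame with columns `sample_id`, `phenotype`, `target`,
#'   `housekeeping` (assay id or `"mean"`), `delta_ct`; samples skipped for
#'   missing measurements are listed in `attr(result, "skipped")`.
#' @export
compute_delta_ct <- function(records, target, housekeeping,
                             reference_mode = c("per_gene", "mean")) {
  reference_mode <- match.arg(reference_mode)
  stopifnot(length(target) == 1L, length(housekeeping) >= 1L)
  records <- records[records$assay %in% c(target, housekeeping), , drop = FALSE]
  # replicate averaging before subtraction
  avg <- stats::aggregate(ct ~ sample_id + phenotype + assay,
                          data = records, FUN = mean)
  samples <- unique(avg[c("sample_id", "phenotype")])
  out <- list(); skipped <- character()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    rows <- avg[avg$sample_id == sid, ]
    ct_t <- rows$ct[rows$assay == target]
    ct_h <- stats::setNames(
      vapply(housekeeping, function(h) {
        v <- rows$ct[rows$assay == h]
        if (length(v) == 1) v else NA_real_
      }, numeric(1)), housekeeping)
    if (length(ct_t) != 1 || anyNA(ct_h)) {
      skipped <- c(skipped, sid)
      next
    }
    if (reference_mode == "per_gene") {
      out[[sid]] <- data.frame(sample_id = sid, phenotype = samples$phenotype[i],
                               target = target, housekeeping = housekeeping,
                               delta_ct = ct_t - unname(ct_h),
                               stringsAsFactors = FALSE)
    } else {
      out[[sid]] <- data.frame(sample_id = sid, phenotype = samples$phenotype[i],
                               target = target, housekeeping = "mean",
                               delta_ct = ct_t - mean(ct_h),
                               stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(sample_id = character(), phenotype = character(),
                         target = character(), housekeeping = character(),
                         delta_ct = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Summarize delta-Ct values by phenotype group
#'
#' Descriptive summaries only (n, mean, min, max per phenotype and
#' housekeeping reference). No hypothesis test is computed; when either
#' phenotype group has fewer than 3 samples a notice to that effect is
#' attached and emitted, since group sizes that small do not support
#' formal testing.
#'
#' @param deltas data.frame from [compute_delta_ct()].
#' @return data.frame of group summaries with a `notice` attribute (`NULL`
#'   when both groups have at least 3 samples).
#' @export
summarize_by_phenotype <- function(deltas) {
  if (nrow(deltas) == 0) {
    out <- data.frame(phenotype = character(), housekeeping = character(),
                      n = integer(), mean = numeric(), min = numeric(),
                      max = numeric(), stringsAsFactors = FALSE)
    attr(out, "notice") <- "no delta-Ct values to summarize"
    return(out)
  }
  grp <- split(deltas, list(deltas$phenotype, deltas$housekeeping), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(d) {
    data.frame(phenotype = d$phenotype[1], housekeeping = d$housekeeping[1],
               n = length(unique(d$sample_id)),
               mean = mean(d$delta_ct), min = min(d$delta_ct),
               max = max(d$delta_ct), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out <- out[order(out$housekeeping, out$phenotype), , drop = FALSE]
  n_by_pheno <- tapply(deltas$sample_id, deltas$phenotype,
                       function(s) length(unique(s)))
  notice <- NULL
  if (length(n_by_pheno) < 2 || any(n_by_pheno < 3)) {
    notice <- paste0("statistical testing not performed: group sizes (",
                     paste(names(n_by_pheno), n_by_pheno, sep = "=",
                           collapse = ", "),
                     ") are insufficient for a formal comparison")
    message(notice)
  }
  attr(out, "notice") <- notice
  out
}
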