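#' Write / read a simulated campaign on disk
#'
#' Serializes a [simulate_campaign()] result: a `sample_sheet.tsv`
#' (sample_id, role, binder_id, dilution_factor, replicate, trace_path),
#' one trace CSV per measurement (the [write_taylorgram_csv()] dialect),
#' and a `truth.tsv` ground-truth record with the generator seed, so a
#' campaign can be re-scored without the generating session.
#'
#' @param campaign Result of [simulate_campaign()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- campaign$sheet
  sheet$trace_path <- file.path("traces", paste0(sheet$sample_id, ".csv"))
  dir.create(file.path(dir, "traces"), showWarnings = FALSE)
  for (i in seq_len(nrow(sheet)))
    write_taylorgram_csv(campaign$traces[[sheet$sample_id[i]]],
                         file.path(dir, sheet$trace_path[i]))
  utils::write.table(sheet, file.path(dir, "sample_sheet.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  tr <- campaign$truth$binders
  tr$seed <- campaign$seed
  tr$indicator_rh_free_nm <- campaign$truth$indicator_rh_free_nm
  tr$indicator_conc_M <- campaign$truth$indicator_conc_M
  utils::write.table(tr, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_campaign
#' @export
read_campaign <- function(dir) {
  sheet <- utils::read.delim(file.path(dir, "sample_sheet.tsv"),
                             stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "dilution_factor", "replicate", "trace_path")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  traces <- stats::setNames(lapply(sheet$trace_path, function(p)
    read_taylorgram_csv(file.path(dir, p))), sheet$sample_id)
  tr <- utils::read.delim(file.path(dir, "truth.tsv"),
                          stringsAsFactors = FALSE)
  truth <- campaign_truth(
    tr[, c("binder_id", "true_kd_M", "expression_conc_M",
           "complex_rh_nm", "nonspecific_scale")],
    indicator_rh_free_nm = tr$indicator_rh_free_nm[1],
    indicator_conc_M = tr$indicator_conc_M[1],
    dilution_ladder = sort(unique(sheet$dilution_factor[sheet$role == "binder"])),
    replicates = max(sheet$replicate))
  list(sheet = sheet[, setdiff(names(sheet), "trace_path")],
       traces = traces, truth = truth, seed = tr$seed[1])
}
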