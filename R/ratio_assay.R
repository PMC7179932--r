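# qPCR long/short transcript-ratio assay. Both amplicons are normalized to a
# reference transcript (e.g. firefly luciferase): dCT = CT(target) - CT(ref).
# The default combines the two dCTs by DIVISION, ddCT = dCT(long)/dCT(short),
# ratio = 2^ddCT, reproducing the published formula literally. The standard
# Livak combination (subtraction, ratio = 2^(dCT(long) - dCT(short))) is
# available as method = "livak"; the two do not agree in general.

#' Long/short transcript ratio from qPCR cycle thresholds
#'
#' @param ct_long,ct_short,ct_ref cycle-threshold values (cycles) of the
#'   long-isoform amplicon, short-isoform amplicon and reference transcript;
#'   vectorized.
#' @param method `"as_printed"` (default): `2^(dCT_long / dCT_short)`;
#'   `"livak"`: `2^(dCT_long - dCT_short)`.
#' @return numeric ratio(s).
#' @examples
#' long_short_ratio(30, 25, 20)             # ddCT = 10/5 = 2 -> ratio 4
#' long_short_ratio(30, 25, 20, "livak")    # 2^(10 - 5) = 32
#' @export
long_short_ratio <- function(ct_long, ct_short, ct_ref,
                             method = c("as_printed", "livak")) {
  method <- match.arg(method)
  if (any(!is.finite(c(ct_long, ct_short, ct_ref))) ||
      any(c(ct_long, ct_short, ct_ref) <= 0)) {
    stop("validation error: CT values must be finite and > 0")
  }
  d_long <- ct_long - ct_ref
  d_short <- ct_short - ct_ref
  if (method == "as_printed") {
    if (any(d_short == 0)) {
      stop("division-by-zero error: dCT(short) = CT(short) - CT(ref) is 0, ",
           "so ddCT = dCT(long)/dCT(short) is undefined")
    }
    2^(d_long / d_short)
  } else {
    2^(d_long - d_short)
  }
}

#' Per-sample ratios and per-genotype summary from a CT table
#'
#' @param ct_table data.frame with columns `sample`, `genotype`, `ct_long`,
#'   `ct_short`, `ct_ref`.
#' @param method see [long_short_ratio()].
#' @return list: `per_sample` (ct_table plus a `ratio` column) and `summary`
#'   (per-genotype `mean`, `sd`, `n`).
#' @export
ratio_results <- function(ct_table, method = c("as_printed", "livak")) {
  required <- c("sample", "genotype", "ct_long", "ct_short", "ct_ref")
  missing <- setdiff(required, names(ct_table))
  if (length(missing) > 0) {
    stop("validation error: CT table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  ct_table$ratio <- long_short_ratio(ct_table$ct_long, ct_table$ct_short,
                                     ct_table$ct_ref, method)
  agg <- do.call(rbind, lapply(split(ct_table, ct_table$genotype),
                               function(d) {
    data.frame(genotype = d$genotype[1], mean = mean(d$ratio),
               sd = stats::sd(d$ratio), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(per_sample = ct_table, summary = agg)
}

#' Express per-genotype mean ratios relative to a control genotype
#'
#' @param summary data.frame with `genotype` and `mean` columns (from
#'   [ratio_results()]), or a full `ratio_results()` return value.
#' @param control control genotype label; its relative value is 1.
#' @return the summary with a `relative` column added.
#' @export
relative_to_control <- function(summary, control) {
  if (is.list(summary) && !is.data.frame(summary) &&
      !is.null(summary$summary)) {
    summary <- summary$summary
  }
  if (!control %in% summary$genotype) {
    stop("parameter error: control genotype '", control, "' not present")
  }
  ref <- summary$mean[summary$genotype == control]
  summary$relative <- summary$mean / ref
  summary
}
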