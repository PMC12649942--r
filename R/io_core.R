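#' Delta notation for an isotope ratio
#'
#' Converts a measured heavy/light isotope ratio to per-mil delta notation
#' relative to an international standard (VPDB for carbon, atmospheric N2 for
#' nitrogen):
#' \deqn{\delta = \left(\frac{R_{sample} - R_{standard}}{R_{standard}}\right) \times 10^3}
#'
#' @param r_sample Measured isotope ratio (e.g. 13C/12C) of the sample.
#' @param r_standard Isotope ratio of the reference standard; must be > 0.
#' @return Delta value in per mil (permil).
#' @examples
#' delta_value(0.98, 1)   # -20 permil
#' @export
delta_value <- function(r_sample, r_standard) {
  if (!is.numeric(r_sample) || !is.numeric(r_standard))
    stop("isotope ratios must be numeric")
  if (any(!is.finite(r_standard)) || any(r_standard <= 0))
    stop("invalid standard ratio: r_standard must be finite and > 0")
  (r_sample - r_standard) / r_standard * 1000
}

sample_columns <- c("sample_id", "group", "d13C", "d15N", "pctC", "pctN",
                    "cn_ratio", "station")

#' Validate a table of per-individual isotope measurements
#'
#' Checks and normalises a data frame of bulk isotope measurements. Required
#' columns are `sample_id`, `group`, `d13C`, `d15N`; optional columns are
#' `pctC`, `pctN`, `cn_ratio` and `station`. When `%C`/`%N` are present and
#' `cn_ratio` is not, the mass C/N ratio is derived as `pctC / pctN`.
#' Missing or non-finite tracer values are rejected; missing `%C`/`%N` are
#' tolerated (the C/N filter then keeps such samples with a flag).
#'
#' @param x A data frame.
#' @return The validated data frame with all optional columns present
#'   (filled with `NA` where absent) and `cn_ratio` derived where possible.
#' @export
validate_samples <- function(x) {
  x <- as.data.frame(x)
  req <- c("sample_id", "group", "d13C", "d15N")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("sample table is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in setdiff(sample_columns, names(x))) x[[col]] <- NA
  x$sample_id <- as.character(x$sample_id)
  x$group <- as.character(x$group)
  if (any(is.na(x$group) | !nzchar(x$group)))
    stop("every sample needs a non-empty group label")
  for (col in c("d13C", "d15N", "pctC", "pctN", "cn_ratio"))
    x[[col]] <- as.numeric(x[[col]])
  if (any(!is.finite(x$d13C)) || any(!is.finite(x$d15N)))
    stop("d13C and d15N must be finite for every sample")
  derive <- is.na(x$cn_ratio) & !is.na(x$pctC) & !is.na(x$pctN)
  x$cn_ratio[derive] <- x$pctC[derive] / x$pctN[derive]
  if (any(!is.na(x$cn_ratio) & x$cn_ratio <= 0))
    stop("cn_ratio must be > 0 when present")
  x[, sample_columns]
}

#' Read / write sample tables
#'
#' Plain UTF-8 CSV (or TSV) with header
#' `sample_id,group,d13C,d15N,pctC,pctN,station`; numeric fields use a decimal
#' point. Values are written at full double precision so a write/read
#' round-trip preserves them.
#'
#' @param path File path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `read_samples` returns a validated sample data frame.
#' @export
read_samples <- function(path, sep = ",") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_samples(x)
}

#' @rdname read_samples
#' @param x Sample table (validated or coercible).
#' @export
write_samples <- function(x, path, sep = ",") {
  x <- validate_samples(x)
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Lipid screening by elemental C/N ratio
#'
#' Splits a sample table on the tissue C/N ratio: samples with
#' `cn_ratio > threshold` are excluded (lipid-rich tissue biases d13C);
#' samples without a C/N value cannot be screened and are kept with
#' `cn_flag = "unscreened"`.
#'
#' @param samples Sample table.
#' @param threshold Exclusion threshold (strict `>`); default 3.5.
#' @return A list with elements `kept` and `excluded`; `kept` carries a
#'   `cn_flag` column (`"ok"` or `"unscreened"`).
#' @export
cn_filter <- function(samples, threshold = 3.5) {
  stopifnot(is.numeric(threshold), threshold > 0)
  samples <- validate_samples(samples)
  out <- !is.na(samples$cn_ratio) & samples$cn_ratio > threshold
  kept <- samples[!out, , drop = FALSE]
  kept$cn_flag <- ifelse(is.na(kept$cn_ratio), "unscreened", "ok")
  if (any(is.na(kept$cn_ratio)))
    message(sum(is.na(kept$cn_ratio)),
            " sample(s) lack %C/%N and were kept unscreened")
  list(kept = kept, excluded = samples[out, , drop = FALSE])
}

#' Summarise one group's tracer moments
#'
#' Produces a source-summary row (mean, sample SD with n-1 denominator, n) per
#' tracer for one functional group, the form used for mixing-model
#' end-members.
#'
#' @param samples Sample table.
#' @param group Group label present in `samples`.
#' @return One-row data frame with columns
#'   `name, n, mean_d13C, sd_d13C, mean_d15N, sd_d15N`.
#' @export
summarize_group <- function(samples, group) {
  samples <- validate_samples(samples)
  sub <- samples[samples$group == group, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("missing group: no samples in group '", group, "'")
  n <- nrow(sub)
  sdv <- function(v) if (n == 1L) 0 else stats::sd(v)
  if (n == 1L)
    warning("group '", group, "' has a single sample; SD reported as 0")
  data.frame(name = group, n = n,
             mean_d13C = mean(sub$d13C), sd_d13C = sdv(sub$d13C),
             mean_d15N = mean(sub$d15N), sd_d15N = sdv(sub$d15N),
             stringsAsFactors = FALSE)
}

#' Summarise all groups of a sample table
#'
#' @param samples Sample table.
#' @param groups Optional character vector restricting/ordering the output.
#' @return Source-summary data frame, one row per group.
#' @export
summarize_sources <- function(samples, groups = NULL) {
  samples <- validate_samples(samples)
  if (is.null(groups)) groups <- unique(samples$group)
  out <- do.call(rbind, lapply(groups, function(g) summarize_group(samples, g)))
  rownames(out) <- NULL
  out
}

#' Isotopic niche width as tracer ranges
#'
#' Carbon range (CR) and nitrogen range (NR): the max - min of d13C and d15N
#' within a group, a simple Layman-style niche-width metric.
#'
#' @param samples Sample table.
#' @param group Group label.
#' @return Named numeric vector `c(carbon_range =, nitrogen_range =)` in
#'   per mil.
#' @export
cr_nr <- function(samples, group) {
  samples <- validate_samples(samples)
  sub <- samples[samples$group == group, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("missing group: no samples in group '", group, "'")
  c(carbon_range = max(sub$d13C) - min(sub$d13C),
    nitrogen_range = max(sub$d15N) - min(sub$d15N))
}

#' Validate a source-summary table
#'
#' Columns `name, n, mean_d13C, sd_d13C, mean_d15N, sd_d15N`; names unique,
#' SDs non-negative, n >= 1.
#'
#' @param x Data frame of per-source tracer moments.
#' @return Validated data frame.
#' @export
validate_sources <- function(x) {
  x <- as.data.frame(x)
  req <- c("name", "n", "mean_d13C", "sd_d13C", "mean_d15N", "sd_d15N")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("source table is missing column(s): ", paste(miss, collapse = ", "))
  x$name <- as.character(x$name)
  if (anyDuplicated(x$name)) stop("source names must be unique")
  for (col in req[-1]) x[[col]] <- as.numeric(x[[col]])
  if (any(x$sd_d13C < 0) || any(x$sd_d15N < 0))
    stop("source SDs must be non-negative")
  if (any(x$n < 1)) stop("source n must be >= 1")
  x[, req]
}

#' Read / write source-summary tables
#'
#' CSV with header `name,n,mean_d13C,sd_d13C,mean_d15N,sd_d15N`, one row per
#' candidate source.
#'
#' @param path File path.
#' @return `read_sources` returns a validated source-summary data frame.
#' @export
read_sources <- function(path) {
  validate_sources(utils::read.csv(path, stringsAsFactors = FALSE,
                                   fileEncoding = "UTF-8"))
}

#' @rdname read_sources
#' @param x Source-summary table.
#' @export
write_sources <- function(x, path) {
  utils::write.csv(validate_sources(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Trophic discrimination factor specification
#'
#' Per-trophic-step shift (mean and SD, per mil) between diet and consumer
#' tissue for each tracer. The package default, `default_tef()`, is the
#' aquatic-food-web convention Delta13C = 1.0 +/- 0.2 permil,
#' Delta15N = 3.4 +/- 0.2 permil.
#'
#' @param mean_d13C,sd_d13C,mean_d15N,sd_d15N Discrimination mean/SD per tracer.
#' @return An object of class `tef_spec`.
#' @export
tef_spec <- function(mean_d13C, sd_d13C, mean_d15N, sd_d15N) {
  vals <- c(mean_d13C, sd_d13C, mean_d15N, sd_d15N)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("TEF means and SDs must be finite numerics")
  if (sd_d13C < 0 || sd_d15N < 0) stop("TEF SDs must be non-negative")
  structure(list(mean_d13C = mean_d13C, sd_d13C = sd_d13C,
                 mean_d15N = mean_d15N, sd_d15N = sd_d15N),
            class = "tef_spec")
}

#' @rdname tef_spec
#' @export
default_tef <- function() tef_spec(1.0, 0.2, 3.4, 0.2)
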