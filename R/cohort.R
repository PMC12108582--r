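#' Summarise per-tunnel morphometry over a cohort
#'
#' Computes, per compartment (femur/tibia) and per metric, the sample size,
#' mean, SD, minimum and maximum, plus pooled (`overall`) rows across both
#' compartments. Values are kept at full precision; rounding happens only in
#' [render_report()].
#'
#' The default SD convention is the population (divide-by-n) form, which is
#' the convention the shipped worked-example cohort's published summary
#' follows; the sample (n-1) form is available via `sd_type`. A group of one
#' row reports `NA` for either convention's nontrivial use (sample SD
#' undefined; population SD would be a misleading 0).
#'
#' @param table a cohort tibble as returned by [load_cohort_table()], or any
#'   data frame with `compartment` plus numeric metric columns among
#'   `bvtv`, `tb_th`, `tb_sp`, `tb_n`, `volume`, `mgv`.
#' @param sd_type `"population"` or `"sample"`.
#' @return tibble of class `cohort_summary`: columns `compartment`, `metric`,
#'   `n`, `mean`, `sd`, `min`, `max`.
#' @examples
#' tab <- load_cohort_table(system.file("extdata", "table4_cohort.csv",
#'                                      package = "tunnelmorph"))
#' summarize_cohort(tab)
#' @export
summarize_cohort <- function(table, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (is.null(table) || nrow(table) == 0L) abort("cohort table is empty")
  if (!"compartment" %in% names(table)) abort("table must tag compartments")
  metrics <- intersect(c("bvtv", "tb_th", "tb_sp", "tb_n", "volume", "mgv"),
                       names(table))
  if (length(metrics) == 0L) abort("no metric columns found")
  sd_fun <- function(x) {
    if (length(x) < 2L) return(NA_real_)
    if (sd_type == "sample") sd(x)
    else sd(x) * sqrt((length(x) - 1) / length(x))
  }
  long <- tidyr::pivot_longer(
    dplyr::select(table, dplyr::all_of(c("compartment", metrics))),
    dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  per <- dplyr::summarise(
    dplyr::group_by(long, .data$compartment, .data$metric),
    n = dplyr::n(), mean = mean(.data$value), sd = sd_fun(.data$value),
    min = min(.data$value), max = max(.data$value), .groups = "drop")
  pooled <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    n = dplyr::n(), mean = mean(.data$value), sd = sd_fun(.data$value),
    min = min(.data$value), max = max(.data$value), .groups = "drop")
  pooled <- dplyr::mutate(pooled, compartment = "overall", .before = 1)
  out <- dplyr::bind_rows(per, pooled)
  out$metric <- factor(out$metric, levels = metrics)
  out <- dplyr::arrange(out, .data$metric, .data$compartment)
  out$metric <- as.character(out$metric)
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Round half away from zero
#'
#' The rounding convention used when rendering cohort reports (plain
#' `round()` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# printed precision per metric: fractions and mm to 3 decimals, Tb.N to 2,
# volume to whole mm3, mGV to 2
report_digits <- c(bvtv = 3L, tb_th = 3L, tb_sp = 3L, tb_n = 2L,
                   volume = 0L, mgv = 2L)

#' Render a cohort summary to CSV or JSON
#'
#' Both formats carry identical numeric content: one record per
#' (compartment, metric) with n, mean, sd, min, max, rounded half away from
#' zero at the metric's printed precision (3 decimals for fractions and mm,
#' 2 for Tb.N and mGV, whole numbers for mm3). Undefined SDs render blank
#' (CSV) / null (JSON).
#'
#' @param summary a `cohort_summary` from [summarize_cohort()].
#' @param fmt `"csv"` or `"json"`.
#' @param path output file.
#' @return invisibly, the rounded tibble that was written.
#' @export
render_report <- function(summary, fmt = c("csv", "json"), path) {
  if (is.character(fmt) && length(fmt) == 1L && !fmt %in% c("csv", "json"))
    abort(sprintf("unknown report format '%s'", fmt))
  fmt <- match.arg(fmt)
  if (is.null(summary) || nrow(summary) == 0L) abort("summary is empty")
  digs <- report_digits[summary$metric]
  digs[is.na(digs)] <- 3L
  out <- summary
  for (cc in c("mean", "sd", "min", "max"))
    out[[cc]] <- round_half_away(out[[cc]], digs)
  if (fmt == "csv") {
    w <- out
    w$sd <- ifelse(is.na(w$sd), "", format_metric(w$sd, digs))
    for (cc in c("mean", "min", "max")) w[[cc]] <- format_metric(w[[cc]], digs)
    write.csv(w, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    recs <- split(out[, setdiff(names(out), c("compartment", "metric"))],
                  paste(out$compartment, out$metric, sep = "."))
    recs <- lapply(recs, function(r) as.list(r))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(out)
}

format_metric <- function(x, digits) {
  vapply(seq_along(x), function(i) {
    if (is.na(x[i])) "" else formatC(x[i], format = "f", digits = digits[i])
  }, character(1))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  NextMethod()
}

#' Plot a cohort summary as per-compartment mean +/- SD ranges
#'
#' @param object a `cohort_summary`.
#' @param ... unused.
#' @return a ggplot object: one facet per metric, point = mean, whiskers =
#'   min/max, thick bar = +/- SD.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  df <- dplyr::filter(object, .data$compartment != "overall")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$compartment, y = .data$mean)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                            linewidth = 0.4, colour = "grey55") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                         ymax = .data$mean + .data$sd),
                            linewidth = 1.4, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Tunnel morphometry by compartment",
                  subtitle = "point = mean, bar = ±SD, whiskers = range") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
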