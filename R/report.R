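# Deterministic HTML / Markdown calibration reports.
#
# The report body contains no timestamps or hostnames, so reruns on
# identical inputs are byte-identical and can be diffed.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fit_table_row <- function(fit) {
  c(fit$analyte, fit$channel,
    formatC(fit$slope, digits = 6, format = "g"),
    formatC(fit$intercept, digits = 6, format = "g"),
    formatC(fit$r_squared, digits = 4, format = "f"),
    formatC(fit$residual_sd, digits = 6, format = "g"),
    as.character(fit$n_points), fit$concentration_unit)
}

measures_table_row <- function(km) {
  c(km$analyte, km$channel, km$unit,
    format_measure(km$lob), format_measure(km$lod), format_measure(km$loq),
    km$definitions_id)
}

html_table <- function(header, rows) {
  head <- paste0("<tr>", paste0("<th>", html_escape(header), "</th>",
                                collapse = ""), "</tr>")
  body <- vapply(rows, function(r) {
    paste0("<tr>", paste0("<td>", html_escape(r), "</td>", collapse = ""),
           "</tr>")
  }, character(1))
  paste0("<table>\n", head, "\n", paste(body, collapse = "\n"), "\n</table>")
}

md_table <- function(header, rows) {
  fmt <- function(r) paste0("| ", paste(r, collapse = " | "), " |")
  paste(c(fmt(header), fmt(rep("---", length(header))),
          vapply(rows, fmt, character(1))), collapse = "\n")
}

plot_fit_png <- function(fit, path, width = 480, height = 360) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  d <- fit$data
  graphics::plot(d$concentration, d$mean_auc,
                 xlab = sprintf("concentration [%s]", fit$concentration_unit),
                 ylab = "corrected band AUC",
                 main = sprintf("%s (%s channel)", fit$analyte, fit$channel),
                 pch = 19)
  if (!is.null(d$sd_auc)) {
    graphics::arrows(d$concentration, d$mean_auc - d$sd_auc,
                     d$concentration, d$mean_auc + d$sd_auc,
                     angle = 90, code = 3, length = 0.04)
  }
  graphics::abline(a = fit$intercept, b = fit$slope, col = "firebrick")
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "R² = %.4f", fit$r_squared))
  invisible(path)
}

#' Render the calibration report
#'
#' Writes a self-contained HTML report and a Markdown twin: per-analyte
#' calibration table (slope, intercept, R-squared, residual sd, n), the
#' key-measures table (with `"Negative"` labels where a limit maps below
#' zero concentration), calibration scatter plots with the fitted line, the
#' run configuration and the package version. Deterministic given identical
#' inputs: no timestamps in the body.
#'
#' @param fits List of [calibration_fit] objects (>= 1).
#' @param measures List of `key_measures` objects, parallel to `fits`
#'   (entries may be `NULL` if measures could not be computed).
#' @param out_path Path of the HTML file; the Markdown twin replaces the
#'   extension with `.md` and plot PNGs are written next to it.
#' @param records Optional merged measurement records, summarised in the
#'   report.
#' @param config Optional named list of run settings echoed verbatim.
#' @param include_plots Embed calibration plots (default TRUE).
#' @return Invisible list with `html` and `markdown` paths.
#' @export
render_report <- function(fits, measures = NULL, out_path = "report.html",
                          records = NULL, config = NULL,
                          include_plots = TRUE) {
  if (length(fits) == 0L) lfa_usage_error("render_report needs at least one fit")
  stopifnot(all(vapply(fits, inherits, logical(1), "calibration_fit")))
  if (is.null(measures)) measures <- vector("list", length(fits))

  version <- as.character(utils::packageVersion("lfaquant"))
  fit_header <- c("Analyte", "Channel", "Slope", "Intercept", "R²",
                  "Residual sd", "n", "Unit")
  fit_rows <- lapply(fits, fit_table_row)
  km_header <- c("Analyte", "Channel", "Unit", "LOB", "LOD", "LOQ",
                 "Definitions")
  km_rows <- lapply(Filter(Negate(is.null), measures), measures_table_row)

  md_path <- paste0(tools::file_path_sans_ext(out_path), ".md")
  plot_paths <- character(0)
  plot_tags <- character(0)
  if (include_plots) {
    for (fit in fits) {
      if (is.null(fit$data)) next
      pp <- sprintf("%s_%s_%s.png", tools::file_path_sans_ext(out_path),
                    gsub("[^A-Za-z0-9]+", "_", fit$analyte), fit$channel)
      plot_fit_png(fit, pp)
      plot_paths <- c(plot_paths, pp)
      b64 <- jsonlite::base64_enc(readBin(pp, "raw", file.info(pp)$size))
      b64 <- gsub("\n", "", b64, fixed = TRUE)
      plot_tags <- c(plot_tags, sprintf(
        '<figure><img src="data:image/png;base64,%s" alt="calibration %s %s"/><figcaption>%s, %s channel</figcaption></figure>',
        b64, fit$analyte, fit$channel, html_escape(fit$analyte), fit$channel))
    }
  }

  summary_lines <- character(0)
  if (!is.null(records)) {
    summary_lines <- sprintf(
      "%d measurement records over %d image(s), %d saturated and excluded by default.",
      nrow(records), length(unique(records$image_id)),
      sum(records$saturated))
  }
  config_lines <- if (!is.null(config)) {
    vapply(names(config), function(k) sprintf("%s = %s", k,
           paste(format(config[[k]]), collapse = ", ")), character(1))
  } else character(0)

  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    "<title>LFA calibration report</title>",
    "<style>body{font-family:sans-serif;max-width:60em;margin:2em auto}",
    "table{border-collapse:collapse}td,th{border:1px solid #999;padding:4px 8px}</style>",
    "</head><body>",
    "<h1>LFA calibration report</h1>",
    sprintf("<p>Generated by lfaquant %s.</p>", version),
    if (length(summary_lines)) paste0("<p>", html_escape(summary_lines), "</p>"),
    "<h2>Calibration fits</h2>",
    html_table(fit_header, fit_rows),
    if (length(km_rows)) c("<h2>Key measures</h2>",
                           html_table(km_header, km_rows)),
    if (length(plot_tags)) c("<h2>Calibration curves</h2>", plot_tags),
    if (length(config_lines)) c("<h2>Run configuration</h2>", "<pre>",
                                html_escape(config_lines), "</pre>"),
    "</body></html>")
  writeLines(unlist(html), out_path, useBytes = TRUE)

  md <- c(
    "# LFA calibration report",
    "",
    sprintf("Generated by lfaquant %s.", version),
    "",
    summary_lines,
    "",
    "## Calibration fits",
    "",
    md_table(fit_header, fit_rows),
    "",
    if (length(km_rows)) c("## Key measures", "",
                           md_table(km_header, km_rows), ""),
    if (length(plot_paths)) c("## Calibration curves", "",
                              sprintf("![calibration](%s)",
                                      basename(plot_paths)), ""),
    if (length(config_lines)) c("## Run configuration", "", "```",
                                config_lines, "```"))
  writeLines(unlist(md), md_path, useBytes = TRUE)

  invisible(list(html = out_path, markdown = md_path, plots = plot_paths))
}
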