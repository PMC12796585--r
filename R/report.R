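# Static report rendering. HTML is the canonical, bit-stable format; the
# "print" variant adds print CSS so the document can be printed to PDF by
# any browser or HTML-to-PDF tool. Every count cell in a rendered report is
# emitted with class="count" so disclosure-control scans can verify that no
# unsuppressed small count appears anywhere.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

mask_count <- function(x, threshold) {
  ifelse(is.na(x), paste0("&lt;", threshold),
         ifelse(x > 0 & x < threshold, paste0("&lt;", threshold),
                format(x, trim = TRUE)))
}

html_table <- function(df, count_cols = character()) {
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                    collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(names(df), function(nm) {
      v <- df[[nm]][i]
      txt <- if (is.na(v)) "" else as.character(v)
      if (nm %in% count_cols) {
        # pre-masked cells arrive as "&lt;k" or "<k"; keep them escaped
        if (grepl("^(<|&lt;)", txt)) txt <- sub("^<", "&lt;", txt)
        sprintf("<td class=\"count\">%s</td>", txt)
      } else {
        sprintf("<td>%s</td>", html_escape(txt))
      }
    }, character(1))
    paste0("<tr>", paste0(cells, collapse = ""), "</tr>")
  }, character(1))
  paste0("<table>", head_row, paste0(body, collapse = ""), "</table>")
}

render_result <- function(label, r, threshold) {
  out <- r$output
  body <- if (inherits(out, "result_table")) {
    fm <- format(out)
    html_table(fm, count_cols = attr(out, "count_cols"))
  } else if (inherits(out, "rr_scan")) {
    df <- as_tibble(out)
    df$a <- mask_count(df$a, threshold)
    df$b <- mask_count(df$b, threshold)
    df$rr <- sprintf("%.3g", df$rr)
    df$ci_low <- sprintf("%.3g", df$ci_low)
    df$ci_high <- sprintf("%.3g", df$ci_high)
    html_table(df, count_cols = c("a", "b"))
  } else if (inherits(out, "age_comparison")) {
    df <- out$summaries
    df$n <- mask_count(df$n, threshold)
    df$median <- sprintf("%.2f", df$median)
    df$q25 <- sprintf("%.2f", df$q25)
    df$q75 <- sprintf("%.2f", df$q75)
    paste0(html_table(df, count_cols = "n"),
           sprintf("<p>Kruskal&ndash;Wallis: H = %.4g, df = %d, p = %.3g</p>",
                   out$kw$H, out$kw$df, out$kw$p))
  } else if (inherits(out, "consult_report")) {
    df <- out$scores
    df$value <- sprintf("%.2f", df$value)
    df$centile <- sprintf("%.3f", df$centile)
    df$z <- sprintf("%.3f", df$z)
    paste0(sprintf("<p>Patient %s vs %s comparator member(s).</p>",
                   html_escape(out$patient_id),
                   mask_count(out$n$comparator_members, threshold)),
           html_table(df))
  } else if (is.list(out) && !is.null(out$summary)) {
    s <- out$summary
    inc <- s$incidence
    inc$cum_incidence <- sprintf("%.1f%%", 100 * inc$cum_incidence)
    paste0(sprintf("<p>Median time to event: %s</p>",
                   if (s$median_reached) sprintf("%g day(s)", s$median) else "not reached"),
           html_table(inc))
  } else {
    "<p>(unrenderable output)</p>"
  }
  sprintf("<section><h2>%s <small>(%s)</small></h2>%s</section>",
          html_escape(label), html_escape(r$module), body)
}

#' Render a report bundle to a self-contained document
#'
#' Formats: `"html"` (canonical) and `"print"` (identical content with
#' print-oriented CSS, ready for printing to PDF). Suppression is applied
#' before rendering: masked cells appear as `"<threshold"`, never as a raw
#' count, and every rendered count cell carries `class="count"` so the
#' document can be scanned for disclosure-control compliance. The footer
#' carries provenance (dataset and config hashes, seed, package version)
#' and a fixed disclaimer that outputs are statistical associations, not
#' causal findings.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param path output file path.
#' @param format `"html"` or `"print"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(bundle, path, format = c("html", "print")) {
  if (!is.character(format) || !format[1] %in% c("html", "print")) {
    abort(paste0("unsupported report format `", format[1],
                 "`; available formats: html, print"))
  }
  format <- format[1]
  thr <- bundle$threshold
  css <- paste(
    "body{font-family:sans-serif;max-width:60em;margin:2em auto;}",
    "table{border-collapse:collapse;margin:1em 0;}",
    "td,th{border:1px solid #999;padding:0.25em 0.6em;text-align:left;}",
    "footer{margin-top:2em;font-size:0.85em;color:#555;}",
    if (format == "print") "@media print{section{page-break-inside:avoid;}}" else ""
  )
  cohort_rows <- if (length(bundle$cohorts)) {
    df <- tibble(cohort = names(bundle$cohorts),
                 members = mask_count(vapply(bundle$cohorts, nrow, integer(1)), thr))
    html_table(df, count_cols = "members")
  } else "<p>No cohorts resolved.</p>"
  sections <- paste0(
    vapply(names(bundle$results),
           function(lb) render_result(lb, bundle$results[[lb]], thr),
           character(1)),
    collapse = "\n"
  )
  err <- if (!is.null(bundle$error)) {
    sprintf("<p class=\"error\"><strong>Pipeline failed</strong> at stage %s: %s</p>",
            html_escape(bundle$error$stage), html_escape(bundle$error$message))
  } else ""
  prov <- bundle$provenance
  html <- sprintf(
    paste0("<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
           "<title>%s</title><style>%s</style></head><body>",
           "<h1>%s</h1>%s<h2>Cohorts</h2>%s\n%s",
           "<footer><p>Outputs are statistical associations computed from ",
           "routinely collected data; they are not causal findings and do not ",
           "by themselves establish clinical implications.</p>",
           "<p>dataset %s | config %s | seed %s | package %s%s</p>",
           "</footer></body></html>"),
    html_escape(bundle$title), css, html_escape(bundle$title), err,
    cohort_rows, sections,
    prov$dataset_hash, prov$config_hash, prov$seed, prov$package_version,
    if (is.null(prov$timestamp)) "" else paste0(" | ", prov$timestamp)
  )
  writeLines(html, path)
  invisible(path)
}

#' Scan a rendered report for unsuppressed small counts
#'
#' Extracts every `class="count"` cell and returns the numeric counts that
#' fall in `1..threshold-1`. An empty result means the document satisfies
#' the small-cell suppression rule.
#'
#' @param path rendered HTML file.
#' @param threshold suppression threshold the document was rendered under.
#' @return numeric vector of violating counts (empty if compliant).
#' @export
scan_report_counts <- function(path, threshold) {
  html <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cells <- regmatches(html, gregexpr("<td class=\"count\">[^<]*</td>", html))[[1]]
  vals <- suppressWarnings(as.numeric(sub("</td>$", "",
                                          sub("^<td class=\"count\">", "", cells))))
  vals <- vals[!is.na(vals)]
  vals[vals > 0 & vals < threshold]
}
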