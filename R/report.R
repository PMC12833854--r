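# three-significant-figure display rounding for report tables
.fmt3 <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else format(signif(v, 3), scientific = FALSE)
  }, character(1))
}

.RATE_COLORS <- c(high = "#d73027", medium = "#fc8d59", low = "#91cf60",
                  very_low = "#4575b4", minimal = "#e0e0e0")

.htmlTable <- function(df, caption = NULL) {
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  head <- paste0("<tr>", paste0("<th>", esc(names(df)), "</th>",
                                collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(df)), function(i)
    paste0("<tr>", paste0("<td>", esc(unlist(df[i, ])), "</td>",
                          collapse = ""), "</tr>"), character(1))
  paste0("<table>",
         if (!is.null(caption)) paste0("<caption>", caption, "</caption>"),
         head, paste(body, collapse = ""), "</table>")
}

.heatmapHtml <- function(m) {
  days <- tgrDays(m); r <- tgrRates(m); n <- length(days)
  rows <- vapply(seq_len(n), function(i) {
    cells <- vapply(seq_len(n), function(j) {
      v <- r[i, j]
      if (is.na(v)) return("<td></td>")
      cls <- as.character(classifyRate(v))
      sprintf("<td style=\"background:%s\">%s</td>",
              .RATE_COLORS[[cls]], .fmt3(v))
    }, character(1))
    paste0("<tr><th>", days[i], "</th>", paste(cells, collapse = ""),
           "</tr>")
  }, character(1))
  paste0("<table class=\"tgr\"><caption>TGR matrix: ", tgrOwner(m),
         "</caption><tr><th></th>",
         paste0("<th>", days, "</th>", collapse = ""), "</tr>",
         paste(rows, collapse = ""), "</table>")
}

.legendHtml <- function() {
  labels <- c(high = "high (r &gt; 0.25)",
              medium = "medium (0.15&ndash;0.25)",
              low = "low (0.10&ndash;0.15)",
              very_low = "very low (0.05&ndash;0.10)",
              minimal = "minimal/negative (r &lt; 0.05)")
  paste0("<p class=\"legend\">",
         paste(sprintf(
           "<span style=\"background:%s\">&nbsp;&nbsp;</span> %s",
           .RATE_COLORS[names(labels)], labels), collapse = " &middot; "),
         "</p>")
}

#' Render a static HTML report from a result bundle
#'
#' Writes a single self-contained HTML document: homogeneity scores before
#' and after filtering, the QC flag table, the per-animal fit table with
#' R-squared and validity, the group growth-rate comparison with effect
#' size and confidence interval, group TGR heat maps with the five-bin
#' color scheme, the power table when computed, and a methodology footer
#' listing every threshold used.  All numbers come from the bundle — nothing
#' is recomputed at render time.
#'
#' @param bundle result of [runFullAnalysis()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
renderReport <- function(bundle, path) {
  cfg <- bundle$config
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>Tumor growth analysis report</title><style>",
    "body{font-family:sans-serif;margin:2em;max-width:70em}",
    "table{border-collapse:collapse;margin:1em 0}",
    "td,th{border:1px solid #999;padding:2px 6px;text-align:right}",
    "caption{font-weight:bold;text-align:left}",
    ".legend span{border:1px solid #666}",
    "</style></head><body>",
    "<h1>Tumor growth analysis report</h1>")

  hom <- rbind(as.data.frame(bundle$homogeneity_pre),
               as.data.frame(bundle$homogeneity_post))
  hom[c("cv", "base_score", "factor", "score")] <-
    lapply(hom[c("cv", "base_score", "factor", "score")], .fmt3)
  parts <- c(parts, "<h2>Homogeneity</h2>", .htmlTable(hom))

  parts <- c(parts, "<h2>Outlier flags</h2>")
  fdf <- as.data.frame(bundle$flags)
  parts <- c(parts, if (nrow(fdf)) .htmlTable(fdf) else
    "<p>none detected</p>")

  parts <- c(parts, "<h2>Exponential fits</h2>")
  fits <- as.data.frame(bundle$fits)
  num <- vapply(fits, is.numeric, logical(1))
  fits[num] <- lapply(fits[num], .fmt3)
  parts <- c(parts, .htmlTable(fits))

  rc <- bundle$rate_comparison
  if (!is.null(rc)) {
    parts <- c(parts, "<h2>Growth-rate comparison</h2>")
    if (rc$status == "ok") {
      parts <- c(parts, sprintf(
        paste0("<p>%s (n=%d) vs %s (n=%d): U=%s, p=%s, Cohen's d=%s ",
               "[%s, %s] (%s), reduction=%s%% (signs are %s minus %s).</p>"),
        rc$group_a, rc$n_a, rc$group_b, rc$n_b, .fmt3(rc$U), .fmt3(rc$p),
        .fmt3(rc$d), .fmt3(rc$d_ci[1]), .fmt3(rc$d_ci[2]), rc$d_magnitude,
        .fmt3(rc$percent_reduction), rc$group_a, rc$group_b))
    } else {
      parts <- c(parts, "<p>insufficient valid animals for comparison</p>")
    }
  }

  parts <- c(parts, "<h2>TGR matrices</h2>", .legendHtml())
  for (g in names(bundle$group_matrices))
    parts <- c(parts, .heatmapHtml(bundle$group_matrices[[g]]))

  if (!is.null(bundle$interval_stats)) {
    di <- bundle$interval_stats
    di <- di[di$diagonal & di$status == "ok", , drop = FALSE]
    if (nrow(di)) {
      num <- vapply(di, is.numeric, logical(1))
      di[num] <- lapply(di[num], .fmt3)
      parts <- c(parts, .htmlTable(
        di, "Diagonal intervals (Bonferroni / BH corrected)"))
    }
  }

  if (!is.null(bundle$power)) {
    pw <- bundle$power
    pw[c("power_conventional", "power_exponential")] <-
      lapply(pw[c("power_conventional", "power_exponential")], .fmt3)
    parts <- c(parts, "<h2>Power assessment</h2>", .htmlTable(pw))
  }

  if (!is.null(bundle$predictions) && length(bundle$predictions)) {
    pr <- data.frame(Animal = names(bundle$predictions),
                     Predicted_Weight_g = .fmt3(bundle$predictions))
    parts <- c(parts, sprintf("<h2>Weights standardized to day %s</h2>",
                              cfg$target_day), .htmlTable(pr))
  }

  profLine <- paste(vapply(names(bundle$profiles), function(g) {
    p <- bundle$profiles[[g]]
    sprintf("%s: %s (IQR x%.1f, growth %g%%/day, decline %g%%/day)",
            g, p$level, p$iqr_multiplier, p$growth_limit_pct_per_day,
            p$decline_limit_pct_per_day)
  }, character(1)), collapse = "; ")
  parts <- c(parts, "<h2>Methodology</h2><ul>",
    sprintf("<li>Unit: %s</li>", cfg$unit),
    sprintf("<li>R&sup2; validity threshold: %s</li>", cfg$r2_threshold),
    sprintf("<li>Filter mode: %s (severities: %s)</li>", cfg$filter_mode,
            paste(cfg$severities, collapse = ", ")),
    sprintf("<li>Sensitivity &mdash; %s</li>", profLine),
    sprintf("<li>Homogeneity thresholds: &epsilon;=15, &pi;=30</li>"),
    sprintf("<li>Seed: %d</li>", cfg$seed),
    "</ul>", "</body></html>")

  writeLines(paste(parts, collapse = "\n"), path, useBytes = TRUE)
  invisible(path)
}
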