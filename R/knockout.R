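#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Paired test of `before` vs `after` using the normal approximation with
#' tie-corrected variance and no continuity correction. Differences
#' `d = before - after` are ranked by absolute value *including* zeros
#' (average ranks for ties); ranks of zero differences are then discarded
#' (Pratt's method) and `W+` is the rank sum of the positive differences.
#' With `N` pairs, `m` zeros, and nonzero tie groups of sizes `t`:
#' `E = (N(N+1) - m(m+1))/4`,
#' `Var = (N(N+1)(2N+1) - m(m+1)(2m+1))/24 - sum(t^3 - t)/48`,
#' `z = (W+ - E)/sqrt(Var)` and the p-value is the two-sided normal tail.
#'
#' @param before,after numeric vectors of equal length (>= 2 pairs).
#' @return Object of class `pratt_signed_rank`: list with `n_pairs`,
#'   `n_zero`, `w_plus`, `expectation`, `variance`, `z`, `p_two_sided`,
#'   `degenerate` (`TRUE` when every difference is zero, reported as
#'   `z = 0`, `p = 1`).
#' @export
wilcoxon_pratt <- function(before, after) {
  if (length(before) != length(after)) {
    stop_data("before/after must pair up")
  }
  n <- length(before)
  if (n < 2) stop_data("need at least 2 pairs")
  d <- before - after
  if (anyNA(d)) stop_data("missing values in paired differences")
  r <- rank(abs(d))  # average ranks, zeros included
  zero <- d == 0
  m <- sum(zero)
  w_plus <- sum(r[d > 0])
  expectation <- (n * (n + 1) - m * (m + 1)) / 4
  tie_sizes <- table(r[!zero])
  tie_sizes <- as.numeric(tie_sizes[tie_sizes > 1])
  variance <- (n * (n + 1) * (2 * n + 1) - m * (m + 1) * (2 * m + 1)) / 24 -
    sum(tie_sizes^3 - tie_sizes) / 48
  degenerate <- m == n
  if (degenerate) {
    z <- 0
    p <- 1
  } else if (variance <= 0) {
    stop_data("zero variance with nonzero rank deviation")
  } else {
    z <- (w_plus - expectation) / sqrt(variance)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(n_pairs = n, n_zero = m, w_plus = w_plus,
                 expectation = expectation, variance = variance,
                 z = z, p_two_sided = p, degenerate = degenerate),
            class = "pratt_signed_rank")
}

#' @export
print.pratt_signed_rank <- function(x, ...) {
  cat("Wilcoxon-Pratt signed-rank test (normal approximation)\n")
  cat(sprintf("  n = %d pairs (%d zero differences), W+ = %.1f\n",
              x$n_pairs, x$n_zero, x$w_plus))
  if (x$degenerate) {
    cat("  all differences zero: z = 0, p = 1\n")
  } else {
    cat(sprintf("  z = %.3f, two-sided p = %.3f\n", x$z, x$p_two_sided))
  }
  invisible(x)
}

#' Select the top-k roosts by a centrality measure
#'
#' @param table a [centrality_table()] result.
#' @param k number of roosts to select (>= 1).
#' @param measure `"degree"` or `"closeness"`.
#' @return Character vector of `k` roost names in descending order of the
#'   measure; exact ties are broken lexicographically and any tie group
#'   spanning the selection boundary (or within the selection) is flagged
#'   in the `"ties"` attribute.
#' @export
select_key_roosts <- function(table, k, measure = c("degree", "closeness")) {
  measure <- match.arg(measure)
  if (k < 1) stop_config("k must be >= 1")
  if (k > nrow(table)) stop_config("k exceeds number of roosts")
  val <- switch(measure, degree = table$degree_centrality,
                closeness = table$closeness)
  ord <- order(-val, table$roost)
  sel <- table$roost[ord][seq_len(k)]
  sel_vals <- val[ord][seq_len(k)]
  ties <- table$roost[val %in% sel_vals[duplicated(sel_vals) |
                                          rev(duplicated(rev(sel_vals)))]]
  if (length(ties) > 0) attr(sel, "ties") <- sort(ties)
  sel
}

#' Roost knockout analysis
#'
#' For each listed roost: remove it from the network ([remove_roost()]),
#' recompute both centralities on the reduced network, and test whether the
#' surviving roosts' centralities changed with a Wilcoxon-Pratt signed-rank
#' test pairing each survivor's full-network value (`before`) with its
#' reduced-network value (`after`). `z` is therefore negative when the
#' measure rises after removal.
#'
#' @param network the full `roost_network`.
#' @param removals character vector of distinct roost names to knock out
#'   individually (not cumulatively).
#' @param values `"raw"` (default) tests the exact centrality values;
#'   `"rounded"` rounds both sides half-up to 3 decimals first, mimicking
#'   a test run on table-precision inputs.
#' @return Object of class `knockout_report`: list with `full` (the full
#'   network's [centrality_table()]), `values`, and `removals` — per removed
#'   roost a list with `table` (reduced-network centrality table) and
#'   `tests` (`degree` and `closeness` [wilcoxon_pratt()] results).
#' @export
knockout_analysis <- function(network, removals,
                              values = c("raw", "rounded")) {
  values <- match.arg(values)
  if (anyDuplicated(removals)) stop_data("duplicate removal names")
  missing <- setdiff(removals, network$nodes)
  if (length(missing) > 0) {
    stop_data("removal(s) not in network: ", paste(missing, collapse = ", "))
  }
  full <- centrality_table(network)
  adj <- function(x) if (values == "rounded") round_half_up(x, 3) else x
  res <- list()
  for (roost in removals) {
    reduced_net <- remove_roost(network, roost)
    reduced <- centrality_table(reduced_net)
    survivors <- reduced$roost
    before_deg <- full$degree_centrality[match(survivors, full$roost)]
    before_clo <- full$closeness[match(survivors, full$roost)]
    res[[roost]] <- list(
      table = reduced,
      tests = list(
        degree = wilcoxon_pratt(adj(before_deg), adj(reduced$degree_centrality)),
        closeness = wilcoxon_pratt(adj(before_clo), adj(reduced$closeness))
      )
    )
  }
  structure(list(full = full, values = values, removals = res),
            class = "knockout_report")
}

#' @export
print.knockout_report <- function(x, ...) {
  cat("Roost knockout report (", length(x$removals), " removals, ",
      x$values, " values)\n", sep = "")
  for (roost in names(x$removals)) {
    t <- x$removals[[roost]]$tests
    cat(sprintf("  - %s: degree z = %.3f (p = %.3f); closeness z = %.3f (p = %.3f)\n",
                roost, t$degree$z, t$degree$p_two_sided,
                t$closeness$z, t$closeness$p_two_sided))
  }
  invisible(x)
}

#' Write a knockout report as CSV
#'
#' Wide table mirroring the published layout: one row per roost, a
#' degree/closeness column pair for the full network and for each removal
#' (`NA` marks the removed roost in its own columns), and `z` / `p` footer
#' rows for the signed-rank tests.
#'
#' @param report a [knockout_analysis()] result.
#' @param path output file path.
#' @param digits decimal places for rounding (default `NULL`, no rounding).
#' @export
write_knockout_csv <- function(report, path, digits = NULL) {
  full <- report$full
  roosts <- full$roost
  cols <- list(roost = c(roosts, "z", "p"))
  add <- function(label, deg, clo, zd = NA, pd = NA, zc = NA, pc = NA) {
    cols[[paste0(label, "_degree")]] <<- c(deg, zd, pd)
    cols[[paste0(label, "_closeness")]] <<- c(clo, zc, pc)
  }
  add("all_sites", full$degree_centrality, full$closeness)
  for (roost in names(report$removals)) {
    r <- report$removals[[roost]]
    add(gsub("[^A-Za-z0-9]+", "_", paste("no", roost)),
        r$table$degree_centrality[match(roosts, r$table$roost)],
        r$table$closeness[match(roosts, r$table$roost)],
        r$tests$degree$z, r$tests$degree$p_two_sided,
        r$tests$closeness$z, r$tests$closeness$p_two_sided)
  }
  df <- as.data.frame(cols, check.names = FALSE)
  if (!is.null(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round_half_up, digits = digits)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

knockout_report_to_list <- function(report) {
  list(
    values = report$values,
    full = report$full,
    removals = lapply(report$removals, function(r) {
      list(table = r$table,
           tests = lapply(r$tests, function(t) unclass(t)))
    })
  )
}

#' Write a knockout report as JSON
#'
#' Machine-readable twin of [write_knockout_csv()];
#' [read_knockout_json()] restores it losslessly.
#'
#' @param report a [knockout_analysis()] result.
#' @param path output file path.
#' @export
write_knockout_json <- function(report, path) {
  jsonlite::write_json(knockout_report_to_list(report), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a knockout report from JSON
#'
#' @param path file written by [write_knockout_json()].
#' @return A `knockout_report` object.
#' @export
read_knockout_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  removals <- lapply(x$removals, function(r) {
    list(table = as.data.frame(r$table),
         tests = lapply(r$tests, function(t) {
           structure(t, class = "pratt_signed_rank")
         }))
  })
  structure(list(full = as.data.frame(x$full), values = x$values,
                 removals = removals),
            class = "knockout_report")
}
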