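check_same_nodes <- function(a, b) {
  if (!identical(a$nodes, b$nodes))
    stop("comparison error: node sets differ")
}

#' Per-edge posterior differences between two groups
#'
#' Pairs retained draws index-by-index across the two independent chains
#' (group A minus group B), and summarizes each unordered edge's difference
#' distribution by its mean and equal-tailed credible interval. An edge is
#' flagged significant when the interval excludes zero. Swapping the groups
#' negates means and swaps/negates the interval endpoints exactly.
#'
#' @param sample_a,sample_b [gibbs_sample()] results on the same node set.
#' @param n_draws paired draws to use (default 5000; reduced with a warning
#'   to the shorter chain if needed).
#' @param level credible level (default 0.95).
#' @return an `edge_differences` data frame: `node_i`, `node_j`,
#'   `mean_diff`, `ci_lower`, `ci_upper`, `significant`, `n_draws`.
#' @export
edge_differences <- function(sample_a, sample_b, n_draws = 5000,
                             level = 0.95) {
  check_same_nodes(sample_a, sample_b)
  m <- min(sample_a$n_draws, sample_b$n_draws)
  if (m < n_draws) {
    warning("only ", m, " paired draws available; using ", m)
    n_draws <- m
  }
  alpha <- (1 - level) / 2
  ed <- edge_index(sample_a$nodes)
  out <- ed[, c("node_i", "node_j")]
  res <- t(vapply(seq_len(nrow(ed)), function(k) {
    d <- edge_draws(sample_a, ed$i[k], ed$j[k])[seq_len(n_draws)] -
      edge_draws(sample_b, ed$i[k], ed$j[k])[seq_len(n_draws)]
    c(mean(d), stats::quantile(d, c(alpha, 1 - alpha), names = FALSE))
  }, numeric(3)))
  out$mean_diff <- res[, 1]
  out$ci_lower <- res[, 2]
  out$ci_upper <- res[, 3]
  out$significant <- out$ci_lower > 0 | out$ci_upper < 0
  out$n_draws <- n_draws
  attr(out, "level") <- level
  class(out) <- c("edge_differences", "data.frame")
  out
}

#' Form directional hypotheses from significant exploratory differences
#'
#' One hypothesis per significant edge difference, its direction given by
#' the sign of the exploratory mean difference (positive: group A's partial
#' correlation is larger). Non-significant edges yield no hypothesis. No
#' multiplicity correction is applied across the 55 edges; the
#' exploratory-confirmatory split carries that burden.
#'
#' @param differences an [edge_differences()] result.
#' @return a `directional_hypotheses` data frame: `node_i`, `node_j`,
#'   `direction` (`"a_greater"`/`"b_greater"`), `exploratory_diff`.
#' @export
form_hypotheses <- function(differences) {
  sig <- differences[differences$significant, , drop = FALSE]
  out <- data.frame(node_i = sig$node_i, node_j = sig$node_j,
                    direction = ifelse(sig$mean_diff > 0, "a_greater",
                                       "b_greater"),
                    exploratory_diff = sig$mean_diff,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("directional_hypotheses", "data.frame")
  out
}

#' Directional posterior probabilities on confirmatory samples
#'
#' For each hypothesis, the posterior probability is the fraction of paired
#' confirmatory draws in which the hypothesized inequality holds strictly;
#' exact ties count one half, so `pp(direction) + pp(opposite) = 1`. A
#' hypothesis is confirmed when `pp > threshold` (default 0.95).
#'
#' @param sample_a,sample_b confirmatory [gibbs_sample()] fits for groups A
#'   and B on the same node set as the hypotheses.
#' @param hypotheses a [form_hypotheses()] result (or compatible data
#'   frame).
#' @param threshold confirmation threshold (default 0.95).
#' @return the hypotheses with `pp` and `confirmed` columns appended.
#' @export
posterior_probability <- function(sample_a, sample_b, hypotheses,
                                  threshold = 0.95) {
  check_same_nodes(sample_a, sample_b)
  nodes <- sample_a$nodes
  m <- min(sample_a$n_draws, sample_b$n_draws)
  pp <- numeric(nrow(hypotheses))
  for (k in seq_len(nrow(hypotheses))) {
    i <- match(hypotheses$node_i[k], nodes)
    j <- match(hypotheses$node_j[k], nodes)
    if (is.na(i) || is.na(j))
      stop("comparison error: edge ", hypotheses$node_i[k], "--",
           hypotheses$node_j[k], " absent from node set")
    d <- edge_draws(sample_a, i, j)[seq_len(m)] -
      edge_draws(sample_b, i, j)[seq_len(m)]
    if (hypotheses$direction[k] == "b_greater") d <- -d
    pp[k] <- mean(d > 0) + 0.5 * mean(d == 0)
  }
  out <- hypotheses
  out$pp <- pp
  out$confirmed <- pp > threshold
  attr(out, "threshold") <- threshold
  out
}

#' Classify edges by presence in two selected networks
#'
#' Every unordered node pair is labelled `both`, `a_only`, `b_only` or
#' `neither` according to the two adjacency matrices — the machine-readable
#' twin of a "unique associations by group" summary table.
#'
#' @param est_a,est_b [select_edges()] results on the same node set.
#' @return data frame with `node_i`, `node_j`, `label` and the two groups'
#'   selected partial correlations.
#' @export
shared_edge_report <- function(est_a, est_b) {
  check_same_nodes(est_a, est_b)
  ed <- edge_index(est_a$nodes)
  a <- est_a$adjacency[cbind(ed$i, ed$j)]
  b <- est_b$adjacency[cbind(ed$i, ed$j)]
  data.frame(node_i = ed$node_i, node_j = ed$node_j,
             label = ifelse(a & b, "both",
                            ifelse(a, "a_only",
                                   ifelse(b, "b_only", "neither"))),
             partial_a = est_a$selected_partials[cbind(ed$i, ed$j)],
             partial_b = est_b$selected_partials[cbind(ed$i, ed$j)],
             stringsAsFactors = FALSE)
}

#' Serialize hypotheses to a YAML file (and read them back)
#'
#' Writing between the exploratory and confirmatory stages makes the
#' confirmation step auditable and independently re-runnable.
#'
#' @param hypotheses a [form_hypotheses()] result.
#' @param path YAML file path.
#' @return `path` invisibly / the hypotheses data frame.
#' @export
write_hypotheses <- function(hypotheses, path) {
  recs <- lapply(seq_len(nrow(hypotheses)), function(k)
    list(node_i = hypotheses$node_i[k], node_j = hypotheses$node_j[k],
         direction = hypotheses$direction[k],
         exploratory_diff = hypotheses$exploratory_diff[k]))
  yaml::write_yaml(list(hypotheses = recs), path, precision = 15)
  invisible(path)
}

#' @rdname write_hypotheses
#' @param path YAML file written by [write_hypotheses()].
#' @export
read_hypotheses <- function(path) {
  if (!file.exists(path)) stop("no such hypotheses file: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$hypotheses))
    stop("corrupt hypotheses file: missing 'hypotheses' key")
  recs <- doc$hypotheses
  out <- data.frame(
    node_i = vapply(recs, `[[`, "", "node_i"),
    node_j = vapply(recs, `[[`, "", "node_j"),
    direction = vapply(recs, `[[`, "", "direction"),
    exploratory_diff = vapply(recs, `[[`, 0, "exploratory_diff"),
    stringsAsFactors = FALSE)
  class(out) <- c("directional_hypotheses", "data.frame")
  out
}
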