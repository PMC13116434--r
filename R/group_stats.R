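# Season-wise habitat comparison: Kruskal-Wallis, Dunn's post hoc pairwise
# z tests on mean ranks, Benjamini-Hochberg adjustment, and compact letter
# displays for figure annotation.

check_groups <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length")
  }
  groups <- as.character(groups)
  if (any(!is.finite(values))) stop("values must be finite")
  tab <- table(groups)
  if (length(tab) < 2L) stop("at least two groups required")
  if (any(tab == 0L)) stop("empty group")
  groups
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom. When every observation is identical the tie
#' correction degenerates; by convention the test then reports H = 0,
#' p = 1.
#'
#' @param values Numeric response values.
#' @param groups Group membership, same length as `values`.
#' @return List with `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- check_groups(values, groups)
  k <- length(unique(groups))
  if (length(values) < 3L) stop("at least 3 observations required")
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = k - 1L, p_value = 1, n = length(values)))
  }
  kt <- stats::kruskal.test(values, factor(groups))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(values))
}

#' Dunn's post hoc pairwise comparisons
#'
#' For each pair of groups (A, B), the standardized difference of mean
#' ranks: z = (Rbar_A - Rbar_B) / sqrt((N(N+1)/12 - T) (1/n_A + 1/n_B)),
#' where ranks are mid-ranks over the pooled sample of size N and
#' T = sum(t^3 - t) / (12 (N - 1)) is the tie correction over tie groups of
#' size t. Two-sided p-values come from the standard normal. p-values are
#' returned raw; adjust them with [bh_adjust()] over the family of pairs.
#'
#' @param values Numeric response values.
#' @param groups Group membership.
#' @return Data frame with `group1`, `group2`, `z`, `p_value`, one row per
#'   unordered pair (group1 < group2 in sort order).
#' @export
dunn_posthoc <- function(values, groups) {
  groups <- check_groups(values, groups)
  g <- sort(unique(groups))
  N <- length(values)
  r <- rank(values)  # mid-ranks
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  mean_rank <- tapply(r, groups, mean)
  n_g <- table(groups)
  pairs <- utils::combn(g, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(var_base * (1 / n_g[[a]] + 1 / n_g[[b]]))
    if (se == 0) { z[j] <- 0; p[j] <- 1; next }
    z[j] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_value = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: on sorted p-values,
#' p_adj_(i) = min over j >= i of (m * p_(j) / j), clipped at 1, mapped back
#' to the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (any(!ok)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Compact letter display
#'
#' Assigns letters to groups so that two groups share at least one letter
#' exactly when their pairwise difference is NOT significant. Letters are
#' the maximal cliques of the non-significance graph, enumerated and
#' ordered deterministically, so identical inputs give identical letterings.
#'
#' @param sig A symmetric logical matrix with group names as dimnames;
#'   `TRUE` marks a significant pair. The diagonal is ignored.
#' @return Named character vector of letter strings, one per group, in the
#'   matrix's group order.
#' @export
compact_letters <- function(sig) {
  sig <- as.matrix(sig)
  if (nrow(sig) != ncol(sig)) stop("significance matrix must be square")
  if (is.null(rownames(sig))) {
    rownames(sig) <- colnames(sig) <- paste0("g", seq_len(nrow(sig)))
  }
  if (!isTRUE(all(sig == t(sig)))) stop("significance matrix must be symmetric")
  groups <- rownames(sig)
  k <- length(groups)
  ns <- !sig
  diag(ns) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(ns, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::max_cliques(g)
  # deterministic order: by smallest member index, then lexicographic
  members <- lapply(cl, function(c) sort(as.integer(c)))
  ord <- order(vapply(members, min, integer(1)),
               vapply(members, function(m)
                 paste(sprintf("%03d", m), collapse = ""), character(1)))
  members <- members[ord]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- rep("", k)
  for (ci in seq_along(members)) {
    for (m in members[[ci]]) out[m] <- paste0(out[m], letters_pool[ci])
  }
  names(out) <- groups
  out
}

#' Season-wise habitat comparisons for a survey table
#'
#' Runs, within each season, a Kruskal-Wallis test across habitats on the
#' chosen response, Dunn's pairwise post hoc comparisons with
#' Benjamini-Hochberg adjustment over the habitat pairs of that season, and
#' a compact letter display from the adjusted significance pattern.
#'
#' @param sites A site table (density added if absent).
#' @param response `"density"` (nests/ha, default) or `"nest_count"`.
#' @param alpha Significance level applied to adjusted p-values for the
#'   letter display (default 0.05).
#' @return List with `tests` (per-season H, df, p), `pairwise` (per-season
#'   pair table with raw and adjusted p), `letters` (per-season named
#'   letter vectors).
#' @export
habitat_season_tests <- function(sites, response = c("density", "nest_count"),
                                 alpha = 0.05) {
  response <- match.arg(response)
  sites <- add_density(sites)
  y <- sites[[response]]
  tests <- list(); pairwise <- list(); letters_out <- list()
  for (s in intersect(season_levels(), unique(sites$season))) {
    idx <- sites$season == s
    kw <- kruskal_wallis(y[idx], sites$habitat[idx])
    dn <- dunn_posthoc(y[idx], sites$habitat[idx])
    dn$p_adj <- bh_adjust(dn$p_value)
    habs <- sort(unique(sites$habitat[idx]))
    sig <- matrix(FALSE, length(habs), length(habs),
                  dimnames = list(habs, habs))
    for (j in seq_len(nrow(dn))) {
      s_ij <- dn$p_adj[j] <= alpha
      sig[dn$group1[j], dn$group2[j]] <- s_ij
      sig[dn$group2[j], dn$group1[j]] <- s_ij
    }
    tests[[s]] <- data.frame(season = s, H = kw$H, df = kw$df,
                             p_value = kw$p_value, n = kw$n,
                             stringsAsFactors = FALSE)
    dn$season <- s
    pairwise[[s]] <- dn
    letters_out[[s]] <- compact_letters(sig)
  }
  list(tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
       pairwise = do.call(rbind, c(pairwise, list(make.row.names = FALSE))),
       letters = letters_out)
}
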