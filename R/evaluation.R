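#' ROC curve and AUC
#'
#' Sweeps thresholds over the distinct score values; tied scores move as one
#' block, so the trapezoidal area credits tied positive/negative pairs with
#' one half. The resulting AUC equals the Mann-Whitney U statistic divided
#' by \code{n_pos * n_neg} exactly.
#'
#' @param scores Numeric vector (higher = more likely positive).
#' @param labels Logical (or 0/1) vector of true positives, aligned with
#'   \code{scores}; both classes must be present.
#' @return An object of class \code{roc_result}: list with \code{points}
#'   (data frame \code{fpr}, \code{tpr} from (0,0) to (1,1)) and \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || any(is.na(scores)) ||
      any(is.na(labels))) {
    stop("scores and labels must align and be complete")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  # one ROC point per distinct score (block of ties)
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_block]
  fp <- cumsum(!l)[last_of_block]
  points <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d points)\n", x$auc,
              nrow(x$points)))
  invisible(x)
}

#' One-sided Wilcoxon-Mann-Whitney test
#'
#' Tests whether the positive group's scores are stochastically larger than
#' the negative group's. U counts pairs where the positive score exceeds
#' the negative, plus half the tied pairs. For combined sample sizes up to
#' 20 the p-value is an exact permutation tail over all label assignments;
#' above that a normal approximation with tie correction is used.
#'
#' @param group_pos,group_neg Nonempty numeric score vectors.
#' @param exact_max Combined-size cutoff for exact enumeration, default 20.
#' @return List with \code{u}, \code{p}, \code{method}
#'   (\code{"exact"}/\code{"normal"}), \code{alternative}.
#' @export
mann_whitney_one_sided <- function(group_pos, group_neg, exact_max = 20L) {
  n1 <- length(group_pos)
  n2 <- length(group_neg)
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty")
  all_scores <- c(group_pos, group_neg)
  r <- rank(all_scores, ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  if (n <= exact_max) {
    idx <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(u_all >= u - 1e-9)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(all_scores)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    p <- stats::pnorm((u - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    method <- "normal"
  }
  list(u = u, p = p, method = method,
       alternative = "positive group stochastically larger")
}

#' One-sided hypergeometric overlap test
#'
#' Upper-tail probability of drawing at least the observed overlap between
#' two gene sets from a common universe.
#'
#' @param set_a,set_b Character vectors, both subsets of \code{universe}.
#' @param universe Character vector of the gene universe.
#' @return List with \code{overlap}, \code{size_a}, \code{size_b},
#'   \code{universe_size}, \code{p}.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- unique(universe)
  bad <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(bad) > 0L) {
    stop(sprintf("set members outside the universe: %s",
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  k <- length(intersect(set_a, set_b))
  m <- length(set_a)
  nn <- length(universe) - m
  d <- length(set_b)
  p <- stats::phyper(k - 1, m, nn, d, lower.tail = FALSE)
  list(overlap = k, size_a = m, size_b = d,
       universe_size = length(universe), p = p)
}

#' Spearman agreement between two rankings
#'
#' Spearman rank correlation (average ranks for ties) over the shared gene
#' universe, with a two-sided p-value from the t approximation.
#'
#' @param rank_a,rank_b Named score vectors or \code{ranked_list} objects;
#'   at least 3 shared genes.
#' @return List with \code{rho}, \code{p}, \code{n}.
#' @export
spearman_agreement <- function(rank_a, rank_b) {
  va <- if (is.data.frame(rank_a)) {
    stats::setNames(rank_a$score, rank_a$gene)
  } else rank_a
  vb <- if (is.data.frame(rank_b)) {
    stats::setNames(rank_b$score, rank_b$gene)
  } else rank_b
  shared <- intersect(names(va), names(vb))
  n <- length(shared)
  if (n < 3L) stop("fewer than 3 shared genes")
  rho <- stats::cor(rank(va[shared]), rank(vb[shared]))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}
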