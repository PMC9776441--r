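# Similarity metrics between point clouds: Chamfer distance, exact and
# entropic (Sinkhorn) Earth Mover's distance, the F-score at a distance
# threshold, and the joint training loss that combines them with the
# expansion penalty.

.check_cloud <- function(p, name) {
  p <- as.matrix(p)
  if (nrow(p) == 0L) stop(name, " is empty", call. = FALSE)
  stopifnot(ncol(p) == 3L, all(is.finite(p)))
  p
}

.cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Chamfer distance between two point clouds
#'
#' Symmetric mean nearest-neighbour distance:
#' `0.5 * (mean_x min_y ||x - y|| + mean_y min_x ||x - y||)`. The unsquared
#' L2 norm is used by default; `squared = TRUE` switches both terms to
#' squared distances.
#'
#' @param p1,p2 N x 3 and M x 3 matrices (may differ in size).
#' @param squared use squared L2 distances.
#' @return non-negative scalar.
#' @export
chamfer_distance <- function(p1, p2, squared = FALSE) {
  p1 <- .check_cloud(p1, "p1"); p2 <- .check_cloud(p2, "p2")
  d <- .cross_dist(p1, p2)
  if (squared) d <- d^2
  0.5 * (mean(apply(d, 1L, min)) + mean(apply(d, 2L, min)))
}

#' Earth Mover's distance between equal-size point clouds
#'
#' The minimum over bijections of the mean per-point L2 transport cost.
#' `mode = "exact"` solves the linear assignment problem (shortest
#' augmenting paths; limited to 1024 points). `mode = "approximate"` runs a
#' fixed-iteration log-domain Sinkhorn solver with a geometrically annealed
#' entropic temperature, suitable for use inside training. On uniform random
#' clouds the approximate value stays within 10% relative (plus 0.02
#' absolute) of the exact optimum and, being the cost of a feasible-up-to-
#' rounding plan, does not undershoot the exact value by more than that
#' tolerance.
#'
#' @param p1,p2 N x 3 matrices with the same N.
#' @param mode `"exact"` or `"approximate"`.
#' @param iters Sinkhorn iterations (approximate mode).
#' @return non-negative scalar (mean per-point cost).
#' @export
emd <- function(p1, p2, mode = c("exact", "approximate"), iters = 50L) {
  mode <- match.arg(mode)
  p1 <- .check_cloud(p1, "p1"); p2 <- .check_cloud(p2, "p2")
  if (nrow(p1) != nrow(p2)) {
    stop("EMD requires equal cardinalities (got ", nrow(p1), " and ", nrow(p2),
         "); resample upstream instead", call. = FALSE)
  }
  n <- nrow(p1)
  d <- .cross_dist(p1, p2)
  if (mode == "exact") {
    if (n > 1024L) stop("exact EMD is limited to 1024 points", call. = FALSE)
    a <- solve_lap(d)
    mean(d[cbind(seq_len(n), a)])
  } else {
    plan <- .sinkhorn_plan(d, iters)
    sum(plan * d)
  }
}

# Row-wise log-sum-exp, stabilized by the row maximum.
.row_lse <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

# Log-domain Sinkhorn with annealed epsilon; returns a plan whose rows sum
# exactly to 1/n (total mass 1). The compiled kernel carries the load; the
# plain-R twin below is kept as a readable reference and consistency check.
.sinkhorn_plan <- function(d, iters = 50L) {
  sinkhorn_plan_cpp(d, as.integer(iters))
}

.sinkhorn_plan_r <- function(d, iters = 50L) {
  n <- nrow(d)
  mc <- mean(d)
  if (mc == 0) return(diag(n) / n)
  eps_seq <- mc * exp(seq(log(0.5), log(0.02), length.out = iters))
  loga <- -log(n)
  f <- rep(0, n); g <- rep(0, n)
  for (it in seq_len(iters)) {
    eps <- eps_seq[it]
    nd <- -d / eps
    # f-update: row logsumexp of (g - C)/eps (g broadcast over columns)
    f <- eps * (loga - .row_lse(nd + matrix(g / eps, n, n, byrow = TRUE)))
    # g-update: column logsumexp of (f - C)/eps (f broadcast over rows)
    g <- eps * (loga - .row_lse(t(nd + f / eps)))
  }
  eps <- eps_seq[iters]
  plan <- exp((outer(f, g, "+") - d) / eps)
  plan * (1 / n) / rowSums(plan)
}

#' F-score between a predicted and a ground-truth cloud
#'
#' Precision is the fraction of predicted points within `threshold` of some
#' ground-truth point; recall the converse; the score is their harmonic mean
#' (0 when both are 0). The conventional "@1%" threshold is 1% of the
#' ground-truth bounding-box diagonal, see [fscore_threshold()].
#'
#' @param pred,gt point clouds.
#' @param threshold positive match radius.
#' @return scalar in `[0, 1]`.
#' @export
f_score <- function(pred, gt, threshold) {
  pred <- .check_cloud(pred, "pred"); gt <- .check_cloud(gt, "gt")
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  d <- .cross_dist(pred, gt)
  precision <- mean(apply(d, 1L, min) <= threshold)
  recall <- mean(apply(d, 2L, min) <= threshold)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Match radius for the F-score at a percentage of shape scale
#'
#' @param gt ground-truth cloud.
#' @param pct percentage of the bounding-box diagonal (default 1).
#' @return positive scalar threshold.
#' @export
fscore_threshold <- function(gt, pct = 1) {
  gt <- .check_cloud(gt, "gt")
  diag_len <- sqrt(sum((apply(gt, 2L, max) - apply(gt, 2L, min))^2))
  pct / 100 * diag_len
}

#' Joint training loss
#'
#' `l_joint = EMD(coarse, gt_coarse) + EMD(refine, gt_refine) +
#' alpha * l_expansion`, with `alpha = 0.1` by default. The EMD terms use the
#' approximate solver by default, as during training.
#'
#' @param coarse,refine predicted clouds.
#' @param gt_coarse,gt_refine ground-truth clouds of matching cardinality.
#' @param l_expansion non-negative expansion-penalty value.
#' @param alpha weight of the expansion penalty.
#' @param mode EMD mode, see [emd()].
#' @return a `loss_bundle` list with `l_coarse_emd`, `l_refine_emd`,
#'   `l_expansion`, `alpha`, `l_joint`.
#' @export
joint_loss <- function(coarse, refine, gt_coarse, gt_refine, l_expansion,
                       alpha = 0.1, mode = "approximate") {
  stopifnot(l_expansion >= 0)
  lc <- emd(coarse, gt_coarse, mode = mode)
  lr <- emd(refine, gt_refine, mode = mode)
  structure(list(l_coarse_emd = lc, l_refine_emd = lr,
                 l_expansion = l_expansion, alpha = alpha,
                 l_joint = lc + lr + alpha * l_expansion),
            class = "loss_bundle")
}
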