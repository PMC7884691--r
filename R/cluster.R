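# label 4-connected TRUE pixels of a logical matrix; 0 = background
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L
      cl <- (p - 1L) %/% nr + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
                  if (cl > 1L) p - nr, if (cl < nc) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

# vectorized pooled two-sample t over columns of a x (subject x pixel)
pixelwise_t <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- colSums(sweep(a, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(b, 2, m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2)
}

#' Cluster-thresholded t map of time-frequency power
#'
#' Compares two groups of subject-level (frequency x time) maps with a
#' pooled two-sample t test at every pixel, masks pixels at `p < alpha`,
#' groups surviving pixels into 4-connected clusters (a pixel is one
#' frequency-step x sample cell), and discards clusters smaller than
#' `min_pixels` (default 500).
#'
#' @param group_a,group_b Lists of `tf_map` matrices (or 3-D arrays
#'   `subject x frequency x time`) of identical shape; at least 2 subjects
#'   per group.
#' @param alpha Pixelwise two-sided significance level (default 0.05).
#' @param min_pixels Minimum cluster extent (default 500).
#' @return A `tf_cluster` object: `t_map`, `p_map`, `mask` (retained
#'   pixels), `raw_mask` (pre-extent threshold), `labels`, and a tibble
#'   `clusters` (id, n_pixels, sign, peak |t|).
#' @export
cluster_ttest <- function(group_a, group_b, alpha = 0.05,
                          min_pixels = 500) {
  as_arr <- function(g) {
    if (is.array(g) && length(dim(g)) == 3L) return(g)
    stopifnot(is.list(g))
    array(unlist(lapply(g, as.numeric)),
          dim = c(dim(g[[1]])[1], dim(g[[1]])[2], length(g))) |>
      aperm(c(3, 1, 2))
  }
  a <- as_arr(group_a)
  b <- as_arr(group_b)
  if (!identical(dim(a)[-1], dim(b)[-1])) {
    abort("group maps disagree in shape.")
  }
  if (dim(a)[1] < 2L || dim(b)[1] < 2L) {
    abort("need at least 2 subjects per group.")
  }
  nf <- dim(a)[2]; nt <- dim(a)[3]
  res <- pixelwise_t(matrix(a, nrow = dim(a)[1]),
                     matrix(b, nrow = dim(b)[1]))
  t_map <- matrix(res$t, nf, nt)
  p_map <- matrix(2 * pt(-abs(res$t), res$df), nf, nt)
  raw <- p_map < alpha
  labels <- label_components(raw)
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_pixels)
  mask <- labels %in% keep
  dim(mask) <- dim(raw)
  clusters <- tibble(
    id = keep,
    n_pixels = sizes[keep],
    sign = vapply(keep, function(k) sign(mean(t_map[labels == k])), 0),
    peak_t = vapply(keep, function(k) max(abs(t_map[labels == k])), 0))
  tmpl <- if (is.list(group_a)) group_a[[1]] else NULL
  structure(list(t_map = t_map, p_map = p_map, mask = mask,
                 raw_mask = raw, labels = labels, clusters = clusters,
                 df = res$df, alpha = alpha, min_pixels = min_pixels,
                 freqs = attr(tmpl, "freqs"), times = attr(tmpl, "times")),
            class = "tf_cluster")
}

#' @export
print.tf_cluster <- function(x, ...) {
  cat(sprintf("<tf_cluster> df = %d, alpha = %g, %d cluster(s) >= %d pixels\n",
              x$df, x$alpha, nrow(x$clusters), x$min_pixels))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
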