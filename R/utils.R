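#' Adjusted Rand index between two partitions
#'
#' Used to score recovery of true protein families and virus genera by the
#' clustering stages. Labels are matched by element name when both inputs are
#' named.
#'
#' @param a,b partition label vectors over the same elements.
#' @return ARI (1 = identical partitions, ~0 = random agreement).
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
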