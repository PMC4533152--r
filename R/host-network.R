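#' Build the virus-cluster by host-class incidence matrix
#'
#' Rows are virus clusters with more than `min_vc_size` member sequences;
#' columns are host classes. A cell is 1 when at least one member of the VC
#' was detected in a genome of that host class. Rows or columns left all-zero
#' are dropped with a warning.
#'
#' @param membership named vector (sequence id -> VC id).
#' @param host_class named vector (sequence id -> host class label).
#' @param min_vc_size VCs must have strictly more members than this
#'   (default 10, i.e. "more than 10 sequences").
#' @return binary integer matrix (VC x host class).
#' @export
build_incidence <- function(membership, host_class, min_vc_size = 10) {
  miss <- setdiff(names(membership), names(host_class))
  if (length(miss)) stop("no host class for sequence ", miss[1])
  sizes <- table(as.character(membership))
  keep_vc <- names(sizes)[sizes > min_vc_size]
  if (!length(keep_vc))
    stop("no VC with more than ", min_vc_size, " sequences")
  seqs <- names(membership)[as.character(membership) %in% keep_vc]
  A <- table(vc = as.character(membership[seqs]),
             class = as.character(host_class[seqs]))
  A <- (unclass(A) > 0) + 0L
  empty_r <- rowSums(A) == 0
  empty_c <- colSums(A) == 0
  if (any(empty_r) || any(empty_c))
    warning("dropping ", sum(empty_r), " empty row(s) and ", sum(empty_c),
            " empty column(s)")
  A[!empty_r, !empty_c, drop = FALSE]
}

#' Barber's bipartite modularity Q
#'
#' For a binary incidence matrix A with row margins k, column margins d and
#' fill m, and a partition assigning a module to every row and column,
#' \deqn{Q = (1/m) \sum_{ij} (A_{ij} - k_i d_j / m)\,
#'   \delta(g^r_i, g^c_j).}
#'
#' @param A binary incidence matrix.
#' @param row_modules,col_modules module labels per row and per column.
#' @return Q in `[-1, 1]`.
#' @export
barber_modularity <- function(A, row_modules, col_modules) {
  A <- as.matrix(A)
  m <- sum(A)
  if (m == 0) stop("modularity undefined for an empty matrix")
  stopifnot(length(row_modules) == nrow(A), length(col_modules) == ncol(A))
  B <- A - outer(rowSums(A), colSums(A)) / m
  same <- outer(as.character(row_modules), as.character(col_modules), "==")
  sum(B[same]) / m
}

# one BRIM sweep: given row labels, optimally assign each column, and back
.brim_iterate <- function(A, row_modules, col_modules) {
  m <- sum(A)
  B <- A - outer(rowSums(A), colSums(A)) / m
  repeat {
    mods <- sort(unique(c(row_modules, col_modules)))
    # columns: module maximising the summed row contribution
    Rind <- matrix(vapply(mods, function(g) as.numeric(row_modules == g),
                          numeric(nrow(A))), nrow = nrow(A))
    colscore <- t(B) %*% Rind                   # ncol x nmod
    new_col <- mods[max.col(colscore, ties.method = "first")]
    # rows
    Cind <- matrix(vapply(mods, function(g) as.numeric(new_col == g),
                          numeric(ncol(A))), nrow = ncol(A))
    rowscore <- B %*% Cind
    new_row <- mods[max.col(rowscore, ties.method = "first")]
    q_new <- barber_modularity(A, new_row, new_col)
    q_old <- barber_modularity(A, row_modules, col_modules)
    if (q_new <= q_old + 1e-12) {
      if (q_new > q_old) { row_modules <- new_row; col_modules <- new_col }
      break
    }
    row_modules <- new_row; col_modules <- new_col
  }
  list(row_modules = row_modules, col_modules = col_modules,
       q = barber_modularity(A, row_modules, col_modules))
}

# label propagation on the bipartite graph, giving an initial partition
.lp_init <- function(A) {
  nr <- nrow(A); nc <- ncol(A)
  lab_r <- seq_len(nr)
  lab_c <- nr + seq_len(nc)
  for (sweep in 1:20) {
    changed <- FALSE
    for (j in sample.int(nc)) {
      nb <- which(A[, j] > 0)
      if (!length(nb)) next
      tab <- table(lab_r[nb])
      top <- names(tab)[tab == max(tab)]
      new <- as.integer(sample(top, 1))
      if (new != lab_c[j]) { lab_c[j] <- new; changed <- TRUE }
    }
    for (i in sample.int(nr)) {
      nb <- which(A[i, ] > 0)
      if (!length(nb)) next
      tab <- table(lab_c[nb])
      top <- names(tab)[tab == max(tab)]
      new <- as.integer(sample(top, 1))
      if (new != lab_r[i]) { lab_r[i] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  list(row = lab_r, col = lab_c)
}

#' Bipartite module detection by label-propagation-seeded BRIM
#'
#' Each restart initialises modules by label propagation on the bipartite
#' graph and refines them with BRIM alternation (fix row modules, assign each
#' column to its Q-maximising module; swap sides) until Q stops improving.
#' The best partition over `n_restarts` restarts is returned; results are
#' deterministic given `seed`. The one-module partition is always evaluated
#' as a floor, so the reported Q is never below it.
#'
#' @param A binary incidence matrix.
#' @param n_restarts number of seeded restarts (default 20).
#' @param seed integer seed.
#' @return list with `row_modules`, `col_modules`, `q`.
#' @export
lp_brim <- function(A, n_restarts = 20, seed = 1) {
  A <- as.matrix(A)
  if (sum(A) == 0) stop("empty matrix")
  set.seed(seed)
  best <- .brim_iterate(A, rep(1L, nrow(A)), rep(1L, ncol(A)))
  # maximally fine deterministic start: each row and column its own module
  fine <- .brim_iterate(A, seq_len(nrow(A)),
                        nrow(A) + seq_len(ncol(A)))
  if (fine$q > best$q) best <- fine
  for (r in seq_len(n_restarts)) {
    init <- if (r %% 2 == 1) .lp_init(A) else
      list(row = sample.int(max(2L, min(nrow(A), ncol(A))), nrow(A),
                            replace = TRUE),
           col = sample.int(max(2L, min(nrow(A), ncol(A))), ncol(A),
                            replace = TRUE))
    cand <- .brim_iterate(A, init$row, init$col)
    if (cand$q > best$q) best <- cand
  }
  best
}

#' Permutation null for bipartite modularity
#'
#' Compares the observed lp-BRIM modularity with the distribution obtained on
#' matrices whose one-cells are shuffled uniformly over the grid (fill
#' preserved; margins free). Empty rows or columns arising in a permutation
#' are retained so Q remains comparable. A margin-preserving alternative
#' (curveball swaps via the vegan null models) is available with
#' `scheme = "margin"`.
#'
#' @param A binary incidence matrix.
#' @param n_perm number of permutations (default 99; must be >= 1).
#' @param seed integer seed.
#' @param scheme `"uniform"` (default) or `"margin"`.
#' @param n_restarts restarts passed to [lp_brim()].
#' @return list with `q_obs`, `q_perm` (vector), `summary` (min/mean/max) and
#'   `p` (empirical, `(1 + #(Q_perm >= Q_obs)) / (n_perm + 1)`).
#' @export
permutation_null <- function(A, n_perm = 99, seed = 1,
                             scheme = c("uniform", "margin"),
                             n_restarts = 20) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("'n_perm' must be at least 1")
  A <- as.matrix(A)
  obs <- lp_brim(A, n_restarts = n_restarts, seed = seed)
  m <- sum(A)
  q_perm <- numeric(n_perm)
  if (scheme == "margin") {
    if (!requireNamespace("vegan", quietly = TRUE))
      stop("the 'margin' scheme requires the vegan package")
    nm <- vegan::nullmodel(A, "curveball")
    set.seed(seed + 1L)
    sims <- stats::simulate(nm, nsim = n_perm)
  }
  for (i in seq_len(n_perm)) {
    if (scheme == "uniform") {
      set.seed(seed + i)
      P <- matrix(0L, nrow(A), ncol(A))
      P[sample.int(length(P), m)] <- 1L
    } else {
      P <- sims[, , i]
    }
    q_perm[i] <- lp_brim(P, n_restarts = n_restarts, seed = seed + i)$q
  }
  list(q_obs = obs$q, q_perm = q_perm,
       summary = c(min = min(q_perm), mean = mean(q_perm),
                   max = max(q_perm)),
       p = (1 + sum(q_perm >= obs$q)) / (n_perm + 1))
}
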