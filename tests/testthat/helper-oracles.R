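# Independent oracles used to validate the package's solvers: exhaustive
# alignment enumeration, least-squares topology fitting over all 4-taxon
# trees, and a numeric rigid-body minimiser.

# Exhaustive global affine-gap alignment score: every gap run of length L
# costs open + L * ext (the package's convention). Exponential; inputs must
# be short (<= ~7 residues).
brute_align_score <- function(a, b, submat, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1, j + 1, "M", sc + submat[A[i], B[j]])
    if (i <= length(A))
      rec(i + 1, j, "X", sc - ext - if (identical(prev, "X")) 0 else open)
    if (j <= length(B))
      rec(i, j + 1, "Y", sc - ext - if (identical(prev, "Y")) 0 else open)
  }
  rec(1L, 1L, "", 0)
  best
}

# Least-squares branch fit of every unrooted 4-taxon topology; returns the
# topology (as the pair grouped with taxon 1) minimising the residual sum
# of squares, with its fitted branch lengths.
brute_quartet <- function(d) {
  stopifnot(nrow(d) == 4)
  pairs <- list(c(1, 2), c(1, 3), c(1, 4))
  dv <- c(d[1, 2], d[1, 3], d[1, 4], d[2, 3], d[2, 4], d[3, 4])
  best <- NULL
  for (p in pairs) {
    q <- setdiff(1:4, p)
    # branches: e1..e4 pendant (taxon order 1..4), e5 internal
    path <- function(i, j) {
      row <- numeric(5)
      row[i] <- 1; row[j] <- 1
      same <- (i %in% p) == (j %in% p)
      if (!same) row[5] <- 1
      row
    }
    X <- rbind(path(1, 2), path(1, 3), path(1, 4),
               path(2, 3), path(2, 4), path(3, 4))
    fit <- stats::lm.fit(X, dv)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(pair = p, rss = rss, branches = fit$coefficients)
  }
  best
}

# The 2-taxon side containing the first taxon, in an unrooted 4-taxon tree
# (every non-trivial split is 2|2, so this identifies the topology).
quartet_pair <- function(tree, first = NULL) {
  parts <- ape::prop.part(ape::unroot(tree))
  labs <- attr(parts, "labels")
  if (is.null(first)) first <- sort(labs)[1]
  for (p in parts) {
    if (length(p) == 2) {
      side <- labs[p]
      if (first %in% side) return(sort(side))
      return(sort(setdiff(labs, side)))
    }
  }
  stop("no non-trivial split found")
}

# Numeric rigid-body minimiser: rotation parameterised as a rotation
# vector, multi-start BFGS; independent of the closed-form solver.
brute_rigid_rmsd <- function(x, y, n_starts = 25, seed = 42) {
  rotvec <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    a <- v / th
    K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
                3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(par) {
    R <- rotvec(par[1:3])
    moved <- x %*% t(R) + matrix(par[4:6], nrow(x), 3, byrow = TRUE)
    sqrt(mean(rowSums((moved - y)^2)))
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    p0 <- c(stats::runif(3, -pi, pi), colMeans(y) - colMeans(x))
    res <- tryCatch(stats::optim(p0, obj, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-14)),
                    error = function(e) NULL)
    if (!is.null(res) && res$value < best) best <- res$value
  }
  best
}

# Canonical topology signature (bipartition key set) for comparing trees.
topo_signature <- function(tree) {
  paste(sort(bipartitions(tree)), collapse = ";")
}

# Build a dd_regionmap by hand for feature-level tests.
make_rm <- function(starts, ends, flags, map = NULL, query_id = "q") {
  rm <- data.frame(region = c("nflank", "helix1", "loop", "helix2", "cflank"),
                   start = as.integer(starts), end = as.integer(ends),
                   flag = flags, stringsAsFactors = FALSE)
  attr(rm, "ref_to_query") <- map
  attr(rm, "query_id") <- query_id
  class(rm) <- c("dd_regionmap", "data.frame")
  rm
}

ref_fixture <- function() dd_reference()

extdata <- function(f) system.file("extdata", f, package = "ddscan",
                                   mustWork = TRUE)
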