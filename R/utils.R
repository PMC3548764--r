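# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

svf_stop <- function(msg, class = "svfuse_error") {
  stop(errorCondition(msg, class = c(class, "svfuse_error", "error", "condition")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded generators do not disturb
#' the caller's random-number stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    svf_stop("`seed` must be a single integer", "svfuse_parameter_error")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Reverse complement of character DNA strings (ACGT alphabet).
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || nchar(s) == 0L) return(s)
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s))))
  }, character(1), USE.NAMES = FALSE)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# Connected components from an edge list over 1..n (union-find with
# path compression). Returns an integer component label per node.
connected_components <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  for (k in seq_along(edges_i)) {
    ri <- find(edges_i[k]); rj <- find(edges_j[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

# Triangular(min, mode, max) sampler; used for fragment lengths where
# only the median and range of the library are known.
rtriangular <- function(n, min, mode, max) {
  if (max <= min) return(rep(min, n))
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

# Piecewise-constant profile over [0, len) from additive deltas.
# deltas: data.frame(start, end, delta). Returns data.frame(start, end, value)
# with value = base + sum of overlapping deltas, merged where equal.
piecewise_profile <- function(len, base, deltas) {
  brk <- sort(unique(c(0, len, deltas$start, deltas$end)))
  brk <- brk[brk >= 0 & brk <= len]
  st <- brk[-length(brk)]
  en <- brk[-1]
  val <- rep(base, length(st))
  if (nrow(deltas)) {
    for (k in seq_len(nrow(deltas))) {
      hit <- st >= deltas$start[k] & en <= deltas$end[k]
      val[hit] <- val[hit] + deltas$delta[k]
    }
  }
  keep <- en > st
  st <- st[keep]; en <- en[keep]; val <- val[keep]
  # merge adjacent runs with equal value
  if (length(val) > 1L) {
    run <- cumsum(c(TRUE, val[-1] != val[-length(val)]))
    st <- tapply(st, run, min)
    en <- tapply(en, run, max)
    val <- tapply(val, run, function(v) v[1])
  }
  data.frame(start = as.numeric(st), end = as.numeric(en),
             value = as.numeric(val), row.names = NULL)
}

# midpoint of a half-open interval
interval_mid <- function(lo, hi) (lo + hi) / 2
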