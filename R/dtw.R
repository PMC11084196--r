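#' Encode a binding site as a residue-number series
#'
#' A binding site is compared to others as an ordered number series: its
#' residue numbers sorted ascending. Along the HSA chain this makes the
#' warping distance reflect how far apart two sites sit in sequence.
#'
#' @param site A [binding_site()].
#' @return Strictly increasing integer vector of residue numbers.
#' @export
site_to_series <- function(site) {
  stopifnot(inherits(site, "binding_site"))
  if (nrow(site$residues) == 0L) {
    stopf("binding site '%s' is empty", site$ligand_id)
  }
  sort(unique(site$residues$number))
}

#' Dynamic-time-warping distance between two number series
#'
#' Classic dynamic-programming DTW: local cost `|x - y|`, symmetric steps
#' (match, insert, delete) each adding one local cost term, endpoints
#' anchored, no warping window, no path-length normalisation. The distance
#' is zero iff the series are identical, and symmetric in its arguments.
#'
#' @param s1,s2 Non-empty numeric vectors (ordered series).
#' @return Non-negative alignment cost.
#' @export
#' @examples
#' dtw_distance(c(1, 3), c(1, 2, 3))  # 1
dtw_distance <- function(s1, s2) {
  n <- length(s1)
  m <- length(s2)
  if (n == 0L || m == 0L) stopf("DTW requires non-empty series")
  # cost matrix |x - y|, then DP over (diag, up, left) predecessors
  cost <- abs(outer(s1, s2, "-"))
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    Di <- D[i, ]       # row i of the padded matrix (prefix of s1 length i-1)
    Dc <- D[i + 1L, ]
    for (j in seq_len(m)) {
      Dc[j + 1L] <- cost[i, j] + min(Di[j], Di[j + 1L], Dc[j])
    }
    D[i + 1L, ] <- Dc
  }
  D[n + 1L, m + 1L]
}

#' Pairwise DTW distance matrix for a collection of binding sites
#'
#' @param sites List of [binding_site()] objects (at least two).
#' @return Symmetric matrix with zero diagonal; dimnames are ligand ids.
#' @export
site_distance_matrix <- function(sites) {
  if (length(sites) < 2L) stopf("need at least two sites")
  series <- lapply(sites, site_to_series)
  ids <- vapply(sites, function(s) s$ligand_id, character(1))
  n <- length(series)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- dtw_distance(series[[i]], series[[j]])
    }
  }
  d
}
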