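#' Cut an agglomerative clustering of a distance matrix into k groups
#'
#' Average-linkage agglomeration (via [stats::hclust()]) on a precomputed
#' distance matrix, cut to exactly `k` clusters. Cluster ids are relabelled
#' 1..k in decreasing cluster size, ties broken by the smallest member
#' index, so labels are deterministic.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param k Number of clusters, `1 <= k <= nrow(d)`.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with integer `labels` (named by the matrix dimnames) and
#'   the `hclust` tree.
#' @export
hierarchical_cluster <- function(d, k, linkage = "average") {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stopf("'d' must be square")
  k <- check_count(k, "k", min = 1L)
  if (k > nrow(d)) stopf("k = %d exceeds the number of items (%d)", k,
                         nrow(d))
  h <- hclust(as.dist(d), method = linkage)
  raw <- cutree(h, k = k)
  labels <- relabel_by_size(raw)
  names(labels) <- rownames(d)
  list(labels = labels, tree = h)
}

relabel_by_size <- function(raw) {
  sizes <- tabulate(raw)
  first_member <- vapply(seq_along(sizes), function(g) min(which(raw == g)),
                         integer(1))
  ord <- order(-sizes, first_member)
  new_id <- integer(length(sizes))
  new_id[ord] <- seq_along(sizes)
  new_id[raw]
}

#' Residue frequencies within a binding-site cluster
#'
#' For a cluster of `n` member ligands, each residue's frequency is the
#' number of members whose site contains that residue (presence, not
#' multiplicity). `a` is the number of distinct residues across all member
#' sites. Percentages are `100 * freq / n`.
#'
#' @param members List of [binding_site()] objects (at least one).
#' @return List with `freq` (data.frame: `number`, `aa`, `count`,
#'   `percent`, sorted by decreasing count then residue number), `n`, `a`.
#' @export
#' @examples
#' a <- binding_site("A", c(1, 2)); b <- binding_site("B", c(2, 3))
#' residue_frequency(list(a, b))$freq
residue_frequency <- function(members) {
  if (length(members) < 1L) stopf("cluster must have at least one member")
  n <- length(members)
  all_res <- lapply(members, function(s) s$residues)
  counts <- table(unlist(lapply(all_res, function(r) unique(r$number))))
  numbers <- as.integer(names(counts))
  aa_map <- do.call(rbind, all_res)
  aa <- aa_map$aa[match(numbers, aa_map$number)]
  freq <- data.frame(number = numbers, aa = aa,
                     count = as.integer(counts),
                     percent = 100 * as.integer(counts) / n,
                     stringsAsFactors = FALSE)
  freq <- freq[order(-freq$count, freq$number), , drop = FALSE]
  rownames(freq) <- NULL
  list(freq = freq, n = n, a = nrow(freq))
}

#' Rank ligands within a cluster by shared-residue frequency
#'
#' A ligand's rank score is the sum, over the residues present in its own
#' site, of that residue's within-cluster frequency divided by the cluster
#' size: `R = sum_r f_aa(r)/n` over residues `r` of the ligand's site.
#' Residues absent from the ligand's site contribute nothing (indicator
#' weighting). High `R` marks ligands whose sites are built from the
#' cluster's most shared residues -- the cluster representatives.
#'
#' @param members List of [binding_site()] objects forming one cluster.
#' @param stats Optional precomputed [residue_frequency()] result for
#'   `members`.
#' @return `data.frame` with `ligand_id` and `R`, sorted by decreasing `R`,
#'   ties by `ligand_id`.
#' @export
#' @examples
#' a <- binding_site("A", c(1, 2)); b <- binding_site("B", c(2, 3))
#' rank_ligands(list(a, b))  # both score (1 + 2)/2 = 1.5
rank_ligands <- function(members, stats = residue_frequency(members)) {
  fr <- setNames(stats$freq$count, stats$freq$number)
  rows <- lapply(members, function(s) {
    res <- as.character(unique(s$residues$number))
    if (!all(res %in% names(fr))) {
      stopf("ligand '%s' has residues outside the cluster frequency table",
            s$ligand_id)
    }
    data.frame(ligand_id = s$ligand_id,
               R = sum(fr[res]) / stats$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$R, out$ligand_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster binding sites and rank their ligands
#'
#' End-to-end site-clustering stage: encode each site as a residue-number
#' series, compute the pairwise DTW distance matrix, agglomerate with the
#' chosen linkage, cut into `k` clusters, and compute per-cluster residue
#' frequencies and ligand ranks.
#'
#' @param sites List of [binding_site()] objects.
#' @param k Number of clusters (the screen uses 5).
#' @param linkage Linkage method for [stats::hclust()].
#' @return An object of class `site_clusters`: list with the distance
#'   matrix, `hclust` tree, `k`, named integer `labels`, and per-cluster
#'   `clusters[[i]]` holding `members`, `n`, `a`, `freq` and `ranks`.
#' @seealso [select_representatives()]
#' @export
cluster_sites <- function(sites, k = 5L, linkage = "average") {
  d <- site_distance_matrix(sites)
  hc <- hierarchical_cluster(d, k, linkage)
  ids <- vapply(sites, function(s) s$ligand_id, character(1))
  clusters <- lapply(seq_len(k), function(g) {
    members <- sites[hc$labels == g]
    stats <- residue_frequency(members)
    list(members = vapply(members, function(s) s$ligand_id, character(1)),
         n = stats$n, a = stats$a, freq = stats$freq,
         ranks = rank_ligands(members, stats))
  })
  structure(
    list(distance = d, tree = hc$tree, k = as.integer(k),
         linkage = linkage, labels = hc$labels, clusters = clusters,
         sites = setNames(sites, ids)),
    class = "site_clusters"
  )
}

#' @export
print.site_clusters <- function(x, ...) {
  cat(sprintf("Binding-site clustering: %d sites, %d clusters (%s linkage, DTW distance)\n",
              length(x$labels), x$k, x$linkage))
  for (g in seq_len(x$k)) {
    cl <- x$clusters[[g]]
    top <- head(cl$freq, 3L)
    cat(sprintf("  cluster %d: n = %2d, a = %2d residues; top residues: %s\n",
                g, cl$n, cl$a,
                paste0(top$aa, top$number, " (", round(top$percent, 1), "%)",
                       collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.site_clusters <- function(object, ...) {
  sizes <- vapply(object$clusters, `[[`, integer(1), "n")
  data.frame(cluster = seq_len(object$k), n = sizes,
             a = vapply(object$clusters, `[[`, integer(1), "a"),
             top_ligand = vapply(object$clusters,
                                 function(cl) cl$ranks$ligand_id[1L],
                                 character(1)),
             top_R = vapply(object$clusters,
                            function(cl) cl$ranks$R[1L], numeric(1)))
}

#' @export
plot.site_clusters <- function(x, ...) {
  plot(x$tree, labels = FALSE, hang = -1,
       main = "DTW clustering of predicted HSA binding sites",
       xlab = "ligand sites", sub = "", ...)
  stats::rect.hclust(x$tree, k = x$k)
  invisible(x)
}

#' Select the top-ranked representative ligands of each cluster
#'
#' @param model A `site_clusters` object from [cluster_sites()].
#' @param top_m Number of representatives per cluster; ties at the cut are
#'   broken by lexicographically smaller ligand id.
#' @return `data.frame` with `cluster`, `ligand_id`, `R`.
#' @export
select_representatives <- function(model, top_m = 1L) {
  stopifnot(inherits(model, "site_clusters"))
  top_m <- check_count(top_m, "top_m", min = 1L)
  out <- lapply(seq_len(model$k), function(g) {
    ranks <- model$clusters[[g]]$ranks
    keep <- head(ranks, top_m)
    cbind(cluster = g, keep)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
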