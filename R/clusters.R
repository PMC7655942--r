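# Correlation-based lipid clustering: Spearman correlation, complete-linkage
# hierarchical clustering, and a dynamic hybrid tree cut that detects tight
# dendrogram branches and re-assigns stray singletons.

#' Spearman correlation matrix of a lipid panel
#'
#' Rank correlation (average ranks on ties) between all pairs of columns;
#' invariant to monotone transforms of the raw concentrations, so it can be
#' computed on raw, log or standardized data interchangeably.
#'
#' @param x Numeric matrix (samples x lipids), at least 3 rows, no missing
#'   values.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (nrow(m) < 3) stop("need at least 3 rows")
  if (anyNA(m)) stop("missing values not allowed")
  const <- apply(m, 2, function(v) length(unique(v)) == 1L)
  if (any(const))
    stop("constant column(s), correlation undefined: ",
         paste(colnames(m)[const], collapse = ", "))
  rho <- stats::cor(m, method = "spearman")
  (rho + t(rho)) / 2
}

#' Complete-linkage hierarchical clustering tree
#'
#' Agglomerative clustering where the distance between two clusters is the
#' maximum pairwise distance between their members; under this linkage a
#' cluster's merge height equals its diameter.  Merge heights are
#' non-decreasing.
#'
#' @param d Symmetric distance matrix with zero diagonal (or a
#'   \code{"dist"}), no NaN entries.
#' @return An \code{"hclust"} tree.
#' @export
complete_linkage_tree <- function(d) {
  if (inherits(d, "dist")) dm <- as.matrix(d) else dm <- as.matrix(d)
  if (any(is.nan(dm)) || anyNA(dm)) stop("NaN/NA distances not allowed")
  if (!isSymmetric(unname(dm), tol = 1e-10))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(dm)) > 1e-12))
    stop("distance matrix must have zero diagonal")
  stats::hclust(stats::as.dist(dm), method = "complete")
}

# attach height of each stage-1 branch: the height of the first merge that
# joins any member of the branch with a non-member
.attach_heights <- function(tree, groups) {
  n <- length(groups)
  attach_h <- stats::setNames(rep(Inf, length(unique(groups))),
                              sort(unique(groups)))
  comp <- vector("list", nrow(tree$merge))  # leaf sets of internal nodes
  node_leaves <- function(j) if (j < 0) -j else comp[[j]]
  for (i in seq_len(nrow(tree$merge))) {
    l <- node_leaves(tree$merge[i, 1])
    r <- node_leaves(tree$merge[i, 2])
    comp[[i]] <- c(l, r)
    gl <- unique(groups[l]); gr <- unique(groups[r])
    # any branch whose members get joined with another branch at this merge
    touched <- union(gl, gr)
    if (length(touched) > 1) {
      for (g in touched) {
        key <- as.character(g)
        if (!is.finite(attach_h[key]))
          attach_h[key] <- tree$height[i]
      }
    }
  }
  attach_h
}

#' Dynamic hybrid cut of a correlation dendrogram
#'
#' Two-stage cluster detection on a complete-linkage tree of correlation
#' distances (d = 1 - rho):
#'
#' Stage 1 detects candidate branches as the maximal subtrees whose
#' diameter (equal to their merge height under complete linkage) does not
#' exceed a tightness cutoff controlled by \code{deep_split}; a candidate is
#' accepted as a cluster if it has at least \code{min_cluster_size} members
#' and is separated from the rest of the tree by a height gap of at least
#' \code{min_gap} (attach height minus branch diameter), so loose branches
#' that merge straight into background correlation are rejected.
#'
#' Stage 2 takes every unlabelled lipid and assigns it to the nearest
#' accepted cluster when its average distance to that cluster's members is
#' below the cluster's merging threshold (its diameter); otherwise the lipid
#' stays unassigned (id 0).  Clusters are relabelled 1..K by decreasing
#' size.
#'
#' @param tree \code{"hclust"} tree from [complete_linkage_tree()].
#' @param d Distance matrix used to build the tree.
#' @param min_cluster_size Minimum cluster size (default 2, permissive, as
#'   appropriate for panels where typical clusters hold only a few species).
#' @param deep_split Integer 0..4; deeper splitting lowers the tightness
#'   cutoff (branch diameters of at most 0.95, 0.80, 0.65, 0.50, 0.35
#'   on the 1 - rho scale).
#' @param cut_height Optional explicit tightness cutoff overriding
#'   \code{deep_split}.
#' @param min_gap Minimum separation between a branch and the rest of the
#'   tree (default 0.1).
#' @return Object of class \code{"cluster_assignment"}: list with
#'   \code{labels} (named integer vector, 0 = unassigned), \code{n_clusters}
#'   and \code{params}.
#' @export
dynamic_hybrid_cut <- function(tree, d, min_cluster_size = 2,
                               deep_split = 1, cut_height = NULL,
                               min_gap = 0.1) {
  stopifnot(inherits(tree, "hclust"))
  dm <- as.matrix(d)
  n <- length(tree$order)
  stopifnot(nrow(dm) == n)
  lipids <- if (!is.null(tree$labels)) tree$labels else
    if (!is.null(rownames(dm))) rownames(dm) else as.character(seq_len(n))
  if (is.null(cut_height)) {
    stopifnot(deep_split %in% 0:4)
    cut_height <- c(0.95, 0.80, 0.65, 0.50, 0.35)[deep_split + 1]
  }
  params <- list(distance = "1 - spearman rho",
                 min_cluster_size = min_cluster_size,
                 deep_split = deep_split, cut_height = cut_height,
                 min_gap = min_gap)
  done <- function(labels) {
    names(labels) <- lipids
    structure(list(labels = labels, n_clusters = max(labels),
                   params = params), class = "cluster_assignment")
  }
  if (min_cluster_size > n) {
    warning("min_cluster_size exceeds the number of lipids; ",
            "all lipids unassigned")
    return(done(rep(0L, n)))
  }

  # stage 1: maximal subtrees with diameter <= cut_height
  groups <- if (all(tree$height > cut_height)) seq_len(n)
            else stats::cutree(tree, h = cut_height)
  attach_h <- .attach_heights(tree, groups)
  labels <- rep(0L, n)
  next_id <- 0L
  for (g in sort(unique(groups))) {
    members <- which(groups == g)
    if (length(members) < min_cluster_size) next
    diam <- max(dm[members, members])
    gap <- attach_h[as.character(g)] - diam
    if (is.finite(gap) && gap < min_gap) next
    next_id <- next_id + 1L
    labels[members] <- next_id
  }

  # stage 2: pull in stray lipids that sit within a cluster's diameter
  if (next_id > 0L) {
    cl_members <- split(which(labels > 0L), labels[labels > 0L])
    cl_diam <- vapply(cl_members,
                      function(m) max(dm[m, m]), numeric(1))
    for (i in which(labels == 0L)) {
      avg <- vapply(cl_members,
                    function(m) mean(dm[i, m]), numeric(1))
      best <- which.min(avg)
      if (avg[best] < cl_diam[best])
        labels[i] <- as.integer(names(cl_members)[best])
    }
  }

  # relabel 1..K by decreasing size (stable for ties)
  if (any(labels > 0L)) {
    sizes <- table(labels[labels > 0L])
    new_order <- names(sizes)[order(-sizes, as.integer(names(sizes)))]
    remap <- stats::setNames(seq_along(new_order), new_order)
    labels[labels > 0L] <- remap[as.character(labels[labels > 0L])]
  }
  done(as.integer(labels))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d lipids, %d clusters, %d unassigned\n",
              length(x$labels), x$n_clusters, sum(x$labels == 0L)))
  invisible(x)
}

#' Cluster lipids of one cohort
#'
#' Convenience pipeline: Spearman correlation of the cohort's standardized
#' species matrix, complete-linkage clustering of d = 1 - rho (signed, so
#' cluster members are positively interchangeable proxies for one another),
#' dynamic hybrid tree cut.
#'
#' @param species_matrix Standardized species matrix (samples x lipids).
#' @param ... Passed to [dynamic_hybrid_cut()].
#' @return A \code{"cluster_assignment"}.
#' @export
cluster_lipids <- function(species_matrix, ...) {
  rho <- spearman_matrix(species_matrix)
  d <- 1 - rho
  diag(d) <- 0
  dynamic_hybrid_cut(complete_linkage_tree(d), d, ...)
}

#' Rank lipid clusters by summed incorporation frequency
#'
#' Clusters are ranked by the sum of their members' incorporation
#' frequencies (descending); each cluster is represented by its most
#' frequently incorporated member.  Unassigned lipids (id 0) are treated as
#' singleton clusters.  Clusters with zero total frequency are dropped.
#' Ties in the representative choice or the ranking are broken by the best
#' (lowest) mean within-model AIC rank when supplied, then lexicographic
#' lipid name.
#'
#' @param frequencies Named numeric vector of per-lipid incorporation
#'   frequencies (counts over CV training fits), all non-negative.
#' @param assignment A \code{"cluster_assignment"} covering the same
#'   lipids.
#' @param aic_rank Optional named numeric vector of mean AIC ranks used for
#'   tie-breaking.
#' @return data.frame ordered by rank: \code{cluster_id},
#'   \code{total_frequency}, \code{representative},
#'   \code{representative_frequency}, \code{n_members}, \code{members}
#'   (comma-joined).
#' @export
representative_ranking <- function(frequencies, assignment,
                                   aic_rank = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            !is.null(names(frequencies)), all(frequencies >= 0))
  labels <- assignment$labels
  miss <- setdiff(names(frequencies), names(labels))
  if (length(miss))
    stop("lipids missing from the cluster assignment: ",
         paste(miss, collapse = ", "))
  labels <- labels[names(frequencies)]
  # unassigned lipids become singleton clusters
  singles <- labels == 0L
  eff <- as.character(labels)
  eff[singles] <- paste0("s:", names(frequencies)[singles])
  rank_of <- function(nm) {
    if (is.null(aic_rank)) rep(0, length(nm))
    else ifelse(nm %in% names(aic_rank), aic_rank[nm], Inf)
  }
  rows <- lapply(split(names(frequencies), eff), function(members) {
    f <- frequencies[members]
    ord <- order(-f, rank_of(members), members)
    data.frame(total_frequency = sum(f),
               representative = members[ord[1]],
               representative_frequency = unname(f[ord[1]]),
               n_members = length(members),
               members = paste(members, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$cluster_id <- names(rows)
  out <- out[out$total_frequency > 0, , drop = FALSE]
  if (!nrow(out)) {
    return(data.frame(cluster_id = character(0),
                      total_frequency = numeric(0),
                      representative = character(0),
                      representative_frequency = numeric(0),
                      n_members = integer(0), members = character(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-out$total_frequency, rank_of(out$representative),
               out$representative)
  out <- out[ord, c("cluster_id", "total_frequency", "representative",
                    "representative_frequency", "n_members", "members")]
  rownames(out) <- NULL
  out
}
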