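# Co-expression module detection: variation filter, correlation / topological
# overlap dissimilarity, average-linkage clustering with a deterministic
# dynamic tree cut, module eigengenes and meta-module grouping.

#' Variation filter
#'
#' Keeps genes whose FPKM range (max minus min) across all samples strictly
#' exceeds `min_range`. Genes with near-constant expression carry no usable
#' co-expression signal at small sample sizes.
#'
#' @param study An [expression_study()].
#' @param min_range Minimum range (strict inequality), default 0.05.
#' @return A filtered [expression_study()].
#' @export
variation_filter <- function(study, min_range = 0.05) {
  stopifnot(inherits(study, "expression_study"))
  if (ncol(study$fpkm) < 2L) stop("variation filter needs at least 2 samples")
  rng <- apply(study$fpkm, 1L, function(v) max(v) - min(v))
  keep <- rng > min_range
  log_msg("info", "variation_filter: kept ", sum(keep), " of ", length(keep),
          " genes (range > ", min_range, ")")
  out <- study
  out$fpkm <- study$fpkm[keep, , drop = FALSE]
  out
}

#' Gene-gene dissimilarity
#'
#' Computes a co-expression dissimilarity on log2(FPKM + 1) profiles. The
#' network is unsigned: `method = "cor"` gives `d = 1 - |Pearson r|`;
#' `method = "tom"` first builds the soft-threshold adjacency `a = |r|^power`
#' and converts it to the topological overlap dissimilarity
#' `d_ij = 1 - (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `k_i` is the connectivity of gene i.
#'
#' @param study An [expression_study()] (pre-filtered; zero-variance genes are
#'   an error).
#' @param method `"cor"` (default) or `"tom"`.
#' @param power Soft-threshold power for the TOM adjacency (default 6).
#' @return Symmetric numeric matrix with zero diagonal, values in \[0, 1\].
#' @export
gene_dissimilarity <- function(study, method = c("cor", "tom"), power = 6) {
  method <- match.arg(method)
  if (ncol(study$fpkm) < 3L) stop("need at least 3 samples for correlations")
  x <- t(log_expression(study))   # samples x genes
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s) must be filtered before network construction: ",
         paste(utils::head(colnames(x)[sds == 0], 3), collapse = ", "))
  }
  r <- abs(stats::cor(x))
  r[r > 1] <- 1
  if (method == "cor") {
    d <- 1 - r
  } else {
    a <- r^power
    diag(a) <- 0
    k <- rowSums(a)
    num <- a %*% a + a
    kmin <- outer(k, k, pmin)
    omega <- num / (kmin + 1 - a)
    diag(omega) <- 1
    d <- 1 - omega
  }
  d[d < 0] <- 0
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# Deterministic gap-based dynamic tree cut ("tree" variant).
#
# Walk the average-linkage dendrogram from the root. A branch becomes a module
# when (i) it holds at least min_size genes, (ii) its merge height is at most
# max_core_height (genes inside are mutually close), and (iii) no relative
# height gap of at least split_gap separates two children that could each be a
# module on their own. Branches failing (ii)/(iii) are descended into; leaves
# stranded in branches smaller than min_size go to module 0 (unassigned).
# Ties never arise: the decision depends only on merge heights and sizes, and
# module ids are renumbered by decreasing size, then by lowest gene index.
cut_gap_tree <- function(hc, min_size, max_core_height, split_gap) {
  n <- length(hc$order)
  merge <- hc$merge
  height <- hc$height
  n_nodes <- nrow(merge)
  labels <- integer(n)

  node_size <- numeric(n_nodes)
  node_leaves <- vector("list", n_nodes)
  child_height <- function(id) if (id < 0) 0 else height[id]
  for (i in seq_len(n_nodes)) {
    kids <- merge[i, ]
    leaves <- integer(0)
    for (k in kids) {
      leaves <- c(leaves, if (k < 0) -k else node_leaves[[k]])
    }
    node_leaves[[i]] <- leaves
    node_size[i] <- length(leaves)
  }

  next_module <- 0L
  modules <- list()
  stack <- n_nodes    # start at the root
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (node < 0) next  # singleton leaf: stays unassigned
    leaves <- node_leaves[[node]]
    if (length(leaves) < min_size) next
    h <- height[node]
    kids <- merge[node, ]
    h_kids <- vapply(kids, child_height, numeric(1))
    sz_kids <- vapply(kids, function(k) if (k < 0) 1L else as.integer(node_size[k]),
                      integer(1))
    rel_gap <- if (h <= 0) 0 else (h - max(h_kids)) / h
    splittable <- rel_gap >= split_gap && min(sz_kids) >= min_size
    if (h <= max_core_height && !splittable) {
      modules[[length(modules) + 1L]] <- leaves
    } else {
      stack <- c(stack, kids[1], kids[2])
    }
  }

  if (length(modules)) {
    ord <- order(-lengths(modules),
                 vapply(modules, min, numeric(1)))
    for (m in seq_along(ord)) labels[modules[[ord[m]]]] <- m
  }
  labels
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of a gene dissimilarity followed by
#' a deterministic dynamic tree cut: instead of one fixed cut height, branches
#' of the dendrogram are accepted as modules where the merge-height structure
#' shows a coherent tight cluster, and clusters smaller than
#' `min_module_size` are left unassigned (module 0). See the package vignette
#' for the exact branch-acceptance rule.
#'
#' @param dissim Symmetric dissimilarity matrix (e.g. from
#'   [gene_dissimilarity()]).
#' @param min_module_size Minimum module size (genes).
#' @param max_core_height Maximum merge height of an accepted module branch.
#'   With six samples the null distribution of correlations is wide (for
#'   unrelated genes |r| exceeds 0.9 in about 1.5% of pairs), so genuinely
#'   co-expressed branches must be held to a far tighter standard than the
#'   spurious-correlation sea; the default 0.05 on the 1 - |r| scale demands
#'   within-module correlations around 0.95.
#' @param split_gap Minimum relative height gap at which a branch is split
#'   into two candidate modules rather than accepted whole.
#' @return An object of class `module_partition`: `module` (named integer
#'   vector, 0 = unassigned), `sizes`, the `hclust` tree and the parameters
#'   used.
#' @export
cluster_and_cut <- function(dissim, min_module_size = 30,
                            max_core_height = 0.05, split_gap = 0.15) {
  dissim <- as.matrix(dissim)
  if (nrow(dissim) != ncol(dissim)) stop("dissimilarity must be square")
  genes <- rownames(dissim) %||% paste0("g", seq_len(nrow(dissim)))
  if (nrow(dissim) < 2L || nrow(dissim) < min_module_size) {
    module <- stats::setNames(integer(nrow(dissim)), genes)
    return(structure(list(module = module, sizes = integer(0), tree = NULL,
                          params = list(min_module_size = min_module_size,
                                        max_core_height = max_core_height,
                                        split_gap = split_gap)),
                     class = "module_partition"))
  }
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  labels <- cut_gap_tree(hc, min_module_size, max_core_height, split_gap)
  module <- stats::setNames(labels, genes)
  sizes <- table(module[module > 0])
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  stopifnot(all(sizes >= min_module_size))
  log_msg("info", "cluster_and_cut: ", length(sizes), " modules, ",
          sum(module == 0), " genes unassigned")
  structure(list(module = module, sizes = sizes, tree = hc,
                 params = list(min_module_size = min_module_size,
                               max_core_height = max_core_height,
                               split_gap = split_gap)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d modules over %d genes (%d unassigned)\n",
              length(x$sizes), length(x$module), sum(x$module == 0)))
  if (length(x$sizes)) {
    cat("  sizes:", paste0("M", names(x$sizes), "=", x$sizes, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the module's
#' standardized expression: each gene's log2(FPKM + 1) profile is centred and
#' scaled across samples, and the first right singular vector of the
#' genes-by-samples matrix is returned (unit norm). Its orientation is fixed
#' so that it correlates non-negatively with the module's mean standardized
#' profile; if that correlation is exactly zero the element of largest
#' magnitude is made positive.
#'
#' @param study An [expression_study()] covering the partition's genes.
#' @param partition A [cluster_and_cut()] result (or any named gene -> module
#'   integer vector wrapped in such an object).
#' @return An object of class `eigengene_set`: `eigengenes` (samples x
#'   modules matrix, columns `M1`, `M2`, ...), `var_explained`, and the sample
#'   sheet.
#' @export
compute_eigengenes <- function(study, partition) {
  stopifnot(inherits(study, "expression_study"),
            inherits(partition, "module_partition"))
  mods <- sort(unique(partition$module[partition$module > 0]))
  if (!length(mods)) stop("partition has no assigned modules")
  x <- log_expression(study)
  missing_genes <- setdiff(names(partition$module), rownames(x))
  if (length(missing_genes)) {
    stop("study lacks partitioned gene(s): ",
         paste(utils::head(missing_genes, 3), collapse = ", "))
  }
  n_samp <- ncol(x)
  eig <- matrix(NA_real_, nrow = n_samp, ncol = length(mods),
                dimnames = list(colnames(x), paste0("M", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("M", mods))
  for (i in seq_along(mods)) {
    genes <- names(partition$module)[partition$module == mods[i]]
    m <- x[genes, , drop = FALSE]
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0)) stop("zero-variance gene in module ", mods[i])
    z <- t(scale(t(m)))   # genes x samples, each gene mean 0 sd 1
    if (nrow(z) == 1L) {
      v <- as.numeric(z[1, ]); v <- v / sqrt(sum(v^2))
      ve[i] <- 1
    } else {
      sv <- svd(z, nu = 0, nv = 1)
      v <- sv$v[, 1]
      ve[i] <- sv$d[1]^2 / sum(sv$d^2)
    }
    mean_profile <- colMeans(z)
    orient <- sum(v * (mean_profile - mean(mean_profile)))
    if (orient < 0) {
      v <- -v
    } else if (orient == 0 && v[which.max(abs(v))] < 0) {
      v <- -v
    }
    eig[, i] <- v
  }
  structure(list(eigengenes = eig, var_explained = ve,
                 samples = study$samples),
            class = "eigengene_set")
}

#' @export
print.eigengene_set <- function(x, ...) {
  cat(sprintf("Eigengene set: %d modules x %d samples\n",
              ncol(x$eigengenes), nrow(x$eigengenes)))
  cat("  variance explained:",
      paste0(names(x$var_explained), "=",
             sprintf("%.2f", x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Group modules into meta-modules
#'
#' Modules whose eigengenes are mutually close are grouped: the dissimilarity
#' between two modules is one minus the Pearson correlation of their
#' eigengenes, the modules are clustered by average linkage, and the tree is
#' cut at height `cut`. Modules distant from all others remain solo groups.
#'
#' @param eigs An [compute_eigengenes()] result.
#' @param cut Eigengene-distance cut height (default 0.2).
#' @return An object of class `metamodule_grouping`: `meta` (named character
#'   vector module -> meta-module label `A`, `B`, ...), the dissimilarity
#'   matrix and the tree.
#' @export
group_metamodules <- function(eigs, cut = 0.2) {
  stopifnot(inherits(eigs, "eigengene_set"))
  me <- eigs$eigengenes
  mods <- colnames(me)
  if (length(mods) == 1L) {
    return(structure(list(meta = stats::setNames("A", mods),
                          dissim = matrix(0, 1, 1, dimnames = list(mods, mods)),
                          tree = NULL, cut = cut),
                     class = "metamodule_grouping"))
  }
  d <- 1 - stats::cor(me)
  d[d < 0] <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(hc, h = cut)
  # label meta-modules A, B, ... in order of first module appearance
  first_seen <- unique(grp[mods])
  lab <- stats::setNames(make_meta_labels(length(first_seen)), first_seen)
  meta <- stats::setNames(lab[as.character(grp[mods])], mods)
  log_msg("info", "group_metamodules: ", length(unique(meta)),
          " meta-modules from ", length(mods), " modules")
  structure(list(meta = meta, dissim = d, tree = hc, cut = cut),
            class = "metamodule_grouping")
}

make_meta_labels <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else c(LETTERS, paste0("Z", seq_len(n - 26L)))[seq_len(n)]
}

#' @export
print.metamodule_grouping <- function(x, ...) {
  cat(sprintf("Meta-module grouping (cut at %.2f):\n", x$cut))
  for (g in unique(x$meta)) {
    members <- names(x$meta)[x$meta == g]
    tag <- if (length(members) == 1L) " (solo)" else ""
    cat("  ", g, ": ", paste(members, collapse = ", "), tag, "\n", sep = "")
  }
  invisible(x)
}
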