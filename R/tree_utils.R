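#' Ensure internal nodes carry labels
#'
#' Unlabeled internal nodes get stable labels `nd<k>` where `k` is the
#' ape internal-node number; existing labels are kept.
#'
#' @param tree an `ape::phylo` tree.
#' @return the tree with a complete `node.label`.
#' @export
ensure_node_labels <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  empty <- !nzchar(lab)
  lab[empty] <- paste0("nd", which(empty))
  tree$node.label <- lab
  tree
}

# branch id of each edge = label of the node below it
branch_ids <- function(tree) {
  nt <- length(tree$tip.label)
  ch <- tree$edge[, 2]
  out <- character(length(ch))
  tip <- ch <= nt
  out[tip] <- tree$tip.label[ch[tip]]
  out[!tip] <- tree$node.label[ch[!tip] - nt]
  out
}

# tip labels below edge e
tips_below_edge <- function(tree, e) {
  node <- tree$edge[e, 2]
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
}

#' Canonical key of a bipartition
#'
#' The side not containing the reference taxon (the first taxon in sorted
#' order), members sorted and joined by `"|"`.
#'
#' @param members taxa on one side of the split.
#' @param all_taxa the full leaf universe.
#' @return character key.
#' @export
canonical_split <- function(members, all_taxa) {
  ref <- sort(all_taxa, method = "radix")[1]
  if (ref %in% members) members <- setdiff(all_taxa, members)
  paste(sort(members, method = "radix"), collapse = "|")
}

split_members <- function(key) strsplit(key, "|", fixed = TRUE)[[1]]

#' Non-trivial bipartitions of a tree
#'
#' Each internal branch of the unrooted tree induces a split; splits are
#' canonicalized as the side not containing the reference taxon (first in
#' sorted leaf order). Trivial splits (one leaf / all but one) are omitted.
#'
#' @param tree an `ape::phylo` tree.
#' @return character vector of canonical split keys.
#' @export
tree_splits <- function(tree) {
  tr <- ape::unroot(tree)
  po <- stats::reorder(tr, "postorder")
  nt <- length(po$tip.label)
  below <- vector("list", max(po$edge))
  for (i in seq_len(nt)) below[[i]] <- i
  keys <- character(0)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chd <- po$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[chd]])
    if (chd > nt) {
      sz <- length(below[[chd]])
      if (sz >= 2L && sz <= nt - 2L)
        keys <- c(keys, canonical_split(po$tip.label[below[[chd]]],
                                        po$tip.label))
    }
  }
  unique(keys)
}

#' Bipartition frequencies across a set of trees
#'
#' @param trees list of `ape::phylo` trees over the same leaf set.
#' @return object of class `"split_support"`: `freq` (named vector of
#'   frequencies in `[0, 1]`, names are canonical split keys), `n_samples`,
#'   `taxa`.
#' @export
split_frequencies <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("no trees given")
  taxa <- sort(trees[[1]]$tip.label, method = "radix")
  for (tr in trees)
    if (!identical(sort(tr$tip.label, method = "radix"), taxa))
      stop("trees are not over the same leaf set")
  keys <- unlist(lapply(trees, tree_splits), use.names = FALSE)
  tab <- table(keys)
  split_support(setNames(as.numeric(tab) / length(trees), names(tab)),
                n_samples = length(trees), taxa = taxa)
}

#' Construct a split-support object
#' @param freq named numeric vector (canonical split key -> frequency).
#' @param n_samples number of trees/samples behind the frequencies.
#' @param taxa leaf universe.
#' @return object of class `"split_support"`.
#' @export
split_support <- function(freq, n_samples, taxa) {
  stopifnot(all(freq >= 0 & freq <= 1))
  taxa <- sort(taxa, method = "radix")
  ref <- taxa[1]
  for (k in names(freq)) {
    mem <- split_members(k)
    if (ref %in% mem || !all(mem %in% taxa))
      stop("split key not canonical for the given taxa: ", k)
  }
  structure(list(freq = freq, n_samples = n_samples, taxa = taxa),
            class = "split_support")
}

#' @export
print.split_support <- function(x, ...) {
  cat(sprintf("split_support: %d splits over %d taxa (n = %d)\n",
              length(x$freq), length(x$taxa), x$n_samples))
  invisible(x)
}

#' Majority-rule consensus with support labels
#'
#' The consensus contains exactly the splits with frequency strictly above
#' 0.5 (such splits are always mutually compatible); each internal node is
#' labeled with its split frequency.
#'
#' @param trees list of `ape::phylo` trees over the same leaf set.
#' @return an `ape::phylo` tree with node labels holding the supports.
#' @export
majority_consensus <- function(trees) {
  sup <- split_frequencies(trees)
  taxa <- sup$taxa
  keep <- sup$freq[sup$freq > 0.5]
  clusters <- lapply(names(keep), split_members)
  supports <- as.numeric(keep)
  # splits above 1/2 form a laminar family once canonicalized away from the
  # reference taxon: nest them by containment
  build <- function(S, label) {
    cand <- which(vapply(clusters, function(cl)
      length(cl) < length(S) && all(cl %in% S), logical(1)))
    maximal <- cand[vapply(cand, function(i)
      !any(vapply(cand, function(j)
        j != i && length(clusters[[i]]) < length(clusters[[j]]) &&
          all(clusters[[i]] %in% clusters[[j]]), logical(1))), logical(1))]
    covered <- unlist(clusters[maximal])
    parts <- c(vapply(maximal, function(i)
      build(clusters[[i]], sprintf("%.17g", supports[i])), character(1)),
      sort(setdiff(S, covered), method = "radix"))
    paste0("(", paste(parts, collapse = ","), ")", label)
  }
  ape::read.tree(text = paste0(build(taxa, ""), ";"))
}

#' MaxDiff/MeanDiff between two split-support sets
#'
#' Over the union of splits observed in either support set (an absent
#' split counts as frequency 0), computes the absolute frequency
#' differences; `max_diff` is their maximum and `mean_diff` their
#' arithmetic mean. This is the standard between-chain split-frequency
#' convergence diagnostic.
#'
#' @param a,b [split_support()] objects over the same leaf universe.
#' @return list with `max_diff`, `mean_diff` and the per-split `table`.
#' @export
chain_compare <- function(a, b) {
  stopifnot(inherits(a, "split_support"), inherits(b, "split_support"))
  if (!identical(a$taxa, b$taxa)) stop("leaf universes do not match")
  keys <- union(names(a$freq), names(b$freq))
  if (length(keys) == 0L)
    return(list(max_diff = 0, mean_diff = 0,
                table = data.frame(split = character(0), freq_a = numeric(0),
                                   freq_b = numeric(0), diff = numeric(0))))
  fa <- ifelse(is.na(match(keys, names(a$freq))), 0, a$freq[keys])
  fb <- ifelse(is.na(match(keys, names(b$freq))), 0, b$freq[keys])
  d <- abs(fa - fb)
  list(max_diff = max(d), mean_diff = mean(d),
       table = data.frame(split = keys, freq_a = as.numeric(fa),
                          freq_b = as.numeric(fb), diff = as.numeric(d)))
}

#' Configuration of an amino-acid jackknife analysis
#'
#' @param replicate_columns columns per replicate (default 20000, the
#'   study-scale protocol).
#' @param n_replicates number of replicates (default 100).
#' @param seed integer seed.
#' @param mode `"columns"` (sample columns without replacement) or
#'   `"genes"` (accumulate whole genes until the target, truncating the
#'   last gene).
#' @return object of class `"jackknife_config"`.
#' @export
jackknife_config <- function(replicate_columns = 20000L,
                             n_replicates = 100L, seed = 1L,
                             mode = c("columns", "genes")) {
  stopifnot(replicate_columns >= 1, n_replicates >= 1)
  structure(list(replicate_columns = as.integer(replicate_columns),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), mode = match.arg(mode)),
            class = "jackknife_config")
}

#' Fixed-size jackknife replicates of a supermatrix
#'
#' Each replicate holds `replicate_columns` distinct columns sampled
#' uniformly without replacement (independently across replicates), or, in
#' gene mode, whole genes accumulated in random order until the target size
#' and truncated at the boundary.
#'
#' @param matrix a [supermatrix()].
#' @param config a [jackknife_config()].
#' @return list of [supermatrix()] replicates.
#' @export
jackknife_replicates <- function(matrix, config) {
  stopifnot(inherits(matrix, "supermatrix"),
            inherits(config, "jackknife_config"))
  width <- ncol(matrix$x)
  if (config$replicate_columns > width)
    stop("replicate_columns exceeds matrix width")
  idx <- jackknife_indices(width, matrix$partitions, config)
  lapply(idx, function(cols) slice_columns(matrix, cols))
}

# 0-based column index sets for each replicate
jackknife_indices <- function(width, partitions, config) {
  with_stream(config$seed, "jackknife_replicates", {
    lapply(seq_len(config$n_replicates), function(r) {
      if (config$mode == "columns") {
        sort(sample.int(width, config$replicate_columns)) - 1L
      } else {
        ord <- sample.int(nrow(partitions))
        cols <- integer(0)
        for (gi in ord) {
          cols <- c(cols, partitions$start[gi]:(partitions$end[gi] - 1L))
          if (length(cols) >= config$replicate_columns) break
        }
        cols[seq_len(config$replicate_columns)]
      }
    })
  })
}
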