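#' Standardize a trait matrix
#'
#' Column-wise z-scores with the sample standard deviation (n - 1), the
#' usual preparation before a Euclidean-type distance so traits on
#' different scales (um, cm, ordinal colour codes) weigh equally. Constant
#' columns carry no information and are mapped to zero with a warning.
#'
#' @param traits data frame with a `taxon` column (or row names) and
#'   numeric trait columns; no missing cells.
#' @return tibble with the same columns, traits standardized; attribute
#'   `standardized` set to `TRUE`.
#' @export
standardize_traits <- function(traits) {
  traits <- trait_tibble(traits)
  if (nrow(traits) < 2) {
    abort("Standardization needs at least two taxa.",
          class = "karyohybrid_input_error")
  }
  vars <- setdiff(names(traits), "taxon")
  const <- purrr::map_lgl(traits[vars], ~ stats::sd(.x) == 0)
  if (any(const)) {
    warn(paste0("Constant trait column(s) mapped to zero: ",
                paste(vars[const], collapse = ", ")),
         class = "karyohybrid_constant_trait_warning")
  }
  out <- traits |>
    mutate(across(all_of(vars),
                  ~ if (stats::sd(.x) == 0) rep(0, length(.x))
                    else (.x - mean(.x)) / stats::sd(.x)))
  attr(out, "standardized") <- TRUE
  out
}

trait_tibble <- function(traits) {
  traits <- as.data.frame(traits)
  if (!"taxon" %in% names(traits)) {
    traits <- cbind(taxon = rownames(traits) %||% as.character(seq_len(nrow(traits))),
                    traits)
  }
  vars <- setdiff(names(traits), "taxon")
  if (any(!purrr::map_lgl(traits[vars], is.numeric))) {
    abort("All trait columns must be numeric.", class = "karyohybrid_input_error")
  }
  if (anyNA(traits)) {
    abort("Trait matrix must have no missing cells.",
          class = "karyohybrid_input_error")
  }
  as_tibble(traits)
}

#' Average Euclidean distance between taxa
#'
#' The default `"avg-euclidean"` distance is the root-mean-square trait
#' difference, `d(i,j) = sqrt(mean_k (x_ik - x_jk)^2)`: a plain Euclidean
#' distance divided by `sqrt(p)` so it does not grow with the number of
#' variables. Plain `"euclidean"` is available since a printed
#' dissimilarity range alone cannot disambiguate the scaling convention.
#'
#' @param traits trait data frame (see [standardize_traits()]); a warning
#'   is issued if it does not look standardized.
#' @param method `"avg-euclidean"` (default) or `"euclidean"`.
#' @return `dist` object with taxon labels.
#' @export
trait_distance <- function(traits, method = c("avg-euclidean", "euclidean")) {
  method <- match.arg(method)
  traits <- trait_tibble(traits)
  if (!isTRUE(attr(traits, "standardized"))) {
    warn("Trait matrix does not appear standardized; distances will mix scales.",
         class = "karyohybrid_unstandardized_warning")
  }
  m <- as.matrix(traits[setdiff(names(traits), "taxon")])
  rownames(m) <- traits$taxon
  d <- stats::dist(m, method = "euclidean")
  if (method == "avg-euclidean") d <- d / sqrt(ncol(m))
  d
}

#' UPGMA dendrogram
#'
#' Unweighted pair-group average-linkage clustering: at each step the two
#' closest clusters merge, with cluster-to-cluster distance the arithmetic
#' mean of all member pairwise distances. Node heights are half the merge
#' distance, giving an ultrametric tree whose cophenetic distance between
#' two leaves equals their merge distance. Tied merge candidates are
#' resolved by a fixed scan order, so output is deterministic.
#'
#' @param d a `dist` object or symmetric distance matrix with labels.
#' @return object of class `upgma_tree`: list with `phylo` (an [ape]
#'   tree with branch lengths), `hclust`, and `merge_heights`.
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m)) || any(diag(m) != 0)) {
      abort("Distance matrix must be symmetric with zero diagonal.",
            class = "karyohybrid_input_error")
    }
    d <- stats::as.dist(m)
  }
  if (anyNA(d)) {
    abort("Distance matrix contains NA/NaN.", class = "karyohybrid_input_error")
  }
  if (attr(d, "Size") < 2) {
    abort("UPGMA needs at least two taxa.", class = "karyohybrid_input_error")
  }
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  # as.phylo already halves hclust merge heights: tip depth = merge/2,
  # so tip-to-tip path length through the tree equals the merge distance
  structure(list(phylo = phy, hclust = hc, merge_heights = hc$height / 2),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA dendrogram, ", length(x$phylo$tip.label), " taxa\n", sep = "")
  cat(newick(x), "\n")
  invisible(x)
}

#' Newick string of a UPGMA tree
#'
#' Branch lengths are height differences (parent height minus child
#' height), printed to 6 decimal places.
#'
#' @param x an `upgma_tree`.
#' @return single newick string.
#' @export
newick <- function(x) {
  phy <- x$phylo
  phy$edge.length <- round(phy$edge.length, 6)
  ape::write.tree(phy)
}

#' Cophenetic distances of a UPGMA tree
#'
#' Leaf-to-leaf distance through the tree; for UPGMA this equals the merge
#' distance of the pair's smallest common cluster.
#'
#' @param x an `upgma_tree`.
#' @return symmetric labelled matrix.
#' @export
cophenetic_distances <- function(x) {
  as.matrix(stats::cophenetic(x$hclust))
}

#' @method tidy upgma_tree
#' @export
tidy.upgma_tree <- function(x, ...) {
  hc <- x$hclust
  tibble(step = seq_along(hc$height),
         left = hc$merge[, 1], right = hc$merge[, 2],
         merge_distance = hc$height,
         height = hc$height / 2)
}

#' @method glance upgma_tree
#' @export
glance.upgma_tree <- function(x, ...) {
  tibble(n_taxa = length(x$hclust$labels),
         root_height = max(x$merge_heights),
         min_merge = min(x$hclust$height),
         max_merge = max(x$hclust$height))
}

#' @method autoplot upgma_tree
#' @export
autoplot.upgma_tree <- function(object, ...) {
  hc <- object$hclust
  dend <- stats::as.dendrogram(hc)
  dd <- ggdend_segments(dend)
  ggplot2::ggplot(dd$segments) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y / 2,
                                       xend = .data$xend, yend = .data$yend / 2)) +
    ggplot2::scale_x_continuous(breaks = seq_along(dd$labels), labels = dd$labels) +
    ggplot2::labs(x = NULL, y = "height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# rectangular dendrogram segments without extra dependencies
ggdend_segments <- function(dend) {
  segs <- list()
  walk <- function(node) {
    if (stats::is.leaf(node)) {
      return(list(x = attr(node, "x") %||% 0, y = 0))
    }
    kids <- purrr::map(seq_along(node), ~ walk(node[[.x]]))
    h <- attr(node, "height")
    xs <- purrr::map_dbl(kids, "x")
    ys <- purrr::map_dbl(kids, "y")
    for (i in seq_along(kids)) {
      segs[[length(segs) + 1]] <<- tibble(x = xs[i], y = ys[i], xend = xs[i], yend = h)
    }
    segs[[length(segs) + 1]] <<- tibble(x = min(xs), y = h, xend = max(xs), yend = h)
    list(x = mean(range(xs)), y = h)
  }
  leaf_x <- 0
  dend <- stats::dendrapply(dend, function(n) {
    if (stats::is.leaf(n)) {
      leaf_x <<- leaf_x + 1
      attr(n, "x") <- leaf_x
    }
    n
  })
  walk(dend)
  list(segments = bind_rows(segs), labels = labels(dend))
}

#' Topology of a rooted binary tree as nested label sets
#'
#' Utility for comparing dendrogram shapes independent of rotation: each
#' internal node becomes a sorted pair of its children's label sets.
#'
#' @param x an `upgma_tree` or `phylo` object.
#' @return canonical character representation of the topology.
#' @export
tree_topology <- function(x) {
  phy <- if (inherits(x, "upgma_tree")) x$phylo else x
  children <- split(phy$edge[, 2], phy$edge[, 1])
  ntip <- length(phy$tip.label)
  build <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    kids <- sort(purrr::map_chr(children[[as.character(node)]], build))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  build(ntip + 1L)
}

#' Read a trait table from TSV
#'
#' Rows are taxa (first column `taxon`), remaining columns numeric traits.
#'
#' @param path TSV path.
#' @return tibble.
#' @export
read_traits <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    taxon = readr::col_character(), .default = readr::col_double()))
  trait_tibble(x)
}
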