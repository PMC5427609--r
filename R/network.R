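#' Gene-level zygosity variation profiles
#'
#' For each selected gene and each sample, the arithmetic mean of the
#' sample's ternary genotype codes over the gene's SNPs.  A value near 0
#' means the sample carries mostly major-homozygous genotypes in the gene;
#' values near 1 and 2 mean predominantly heterozygous and alternative-
#' homozygous genotypes.
#'
#' @param tern a [ternary_matrix()].
#' @param gene_map a [map_snps_to_genes()] result on the same sites.
#' @param selected_genes gene ids to profile (default: all genes with SNPs).
#' @return Numeric matrix, samples x genes.
#' @export
gene_variation <- function(tern, gene_map, selected_genes = NULL) {
  if (is.null(selected_genes))
    selected_genes <- names(gene_map$map)[gene_map$n_snps > 0L]
  missing_g <- setdiff(selected_genes, names(gene_map$map))
  if (length(missing_g))
    stop("gene(s) not in map: ", paste(missing_g, collapse = ", "))
  empty <- selected_genes[gene_map$n_snps[selected_genes] == 0L]
  if (length(empty))
    stop("selected gene(s) contain no SNPs: ", paste(empty, collapse = ", "))
  prof <- vapply(selected_genes, function(g)
    rowMeans(tern$G[, gene_map$map[[g]], drop = FALSE]),
    numeric(nrow(tern$G)))
  rownames(prof) <- tern$samples$sample_id
  prof
}

#' Pairwise Pearson correlations of gene profiles
#'
#' Genes whose profile has zero variance across samples are excluded (a
#' Pearson coefficient is undefined for them) and counted in a message.
#'
#' @param profiles samples x genes matrix from [gene_variation()].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(profiles) {
  if (nrow(profiles) < 3L)
    stop("need at least 3 samples for correlations")
  if (ncol(profiles) < 2L)
    stop("need at least 2 genes for correlations")
  v <- apply(profiles, 2, sd)
  if (any(v == 0)) {
    message("correlation_matrix: excluded ", sum(v == 0),
            " zero-variance gene profile(s): ",
            paste(colnames(profiles)[v == 0], collapse = ", "))
    profiles <- profiles[, v > 0, drop = FALSE]
    if (ncol(profiles) < 2L)
      stop("fewer than 2 genes with variance; no correlations")
  }
  cor(profiles)
}

#' Named per-figure threshold presets
#'
#' Positive/negative correlation cutoffs used for the shipped network
#' variants: `wmi` (0.45, -0.25), `wmi_go` (0.8, -0.3),
#' `mi_xpclr` (0.9, -0.4), `mi_xpehh` (0.9, -0.5), `go_strict` (0.97, -0.5).
#' @export
network_presets <- list(
  wmi = c(pos = 0.45, neg = -0.25),
  wmi_go = c(pos = 0.8, neg = -0.3),
  mi_xpclr = c(pos = 0.9, neg = -0.4),
  mi_xpehh = c(pos = 0.9, neg = -0.5),
  go_strict = c(pos = 0.97, neg = -0.5)
)

#' Build a thresholded gene correlation network
#'
#' Genes are nodes; an edge connects genes i < j iff their correlation is
#' strictly larger than `pos_cut` or strictly smaller than `neg_cut`.
#'
#' @param corr correlation matrix from [correlation_matrix()].
#' @param pos_cut,neg_cut strict thresholds, `neg_cut < pos_cut`.
#' @return An object of class `correlation_network`: list with `nodes`,
#'   `edges` (data.frame `gene_i`, `gene_j`, `r`, `sign`), `pos_cut`,
#'   `neg_cut`.
#' @export
build_network <- function(corr, pos_cut = 0.45, neg_cut = -0.25) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr), neg_cut < pos_cut)
  genes <- colnames(corr)
  ut <- upper.tri(corr)
  hit <- ut & (corr > pos_cut | corr < neg_cut)
  idx <- which(hit, arr.ind = TRUE)
  edges <- data.frame(gene_i = genes[idx[, 1]], gene_j = genes[idx[, 2]],
                      r = corr[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_i, edges$gene_j), , drop = FALSE]
  edges$sign <- ifelse(edges$r > 0, "+", "-")
  rownames(edges) <- NULL
  structure(list(nodes = genes, edges = edges,
                 pos_cut = pos_cut, neg_cut = neg_cut),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf(
    "<correlation_network> %d nodes, %d edges (%d positive, %d negative); cuts (%g, %g)\n",
    length(x$nodes), nrow(x$edges), sum(x$edges$sign == "+"),
    sum(x$edges$sign == "-"), x$pos_cut, x$neg_cut))
  invisible(x)
}

#' Rank hub genes by connectivity
#'
#' Genes ranked by total degree, with separate positive- and negative-edge
#' degrees; ties broken by gene id.
#'
#' @param network a [build_network()] result.
#' @param top_k return only the `top_k` highest-degree genes.
#' @return data.frame with `gene_id`, `degree`, `pos_degree`, `neg_degree`.
#' @export
hub_genes <- function(network, top_k = Inf) {
  if (!nrow(network$edges))
    return(data.frame(gene_id = character(), degree = integer(),
                      pos_degree = integer(), neg_degree = integer(),
                      stringsAsFactors = FALSE))
  ends <- c(network$edges$gene_i, network$edges$gene_j)
  sgn <- rep(network$edges$sign, 2L)
  deg <- table(factor(ends, levels = network$nodes))
  pos <- table(factor(ends[sgn == "+"], levels = network$nodes))
  neg <- table(factor(ends[sgn == "-"], levels = network$nodes))
  out <- data.frame(gene_id = network$nodes, degree = as.integer(deg),
                    pos_degree = as.integer(pos),
                    neg_degree = as.integer(neg),
                    stringsAsFactors = FALSE)
  out <- out[out$degree > 0L, , drop = FALSE]
  out <- out[order(-out$degree, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  if (is.finite(top_k)) out <- out[seq_len(min(top_k, nrow(out))), ,
                                   drop = FALSE]
  out
}

#' Export a correlation network
#'
#' `tsv` writes the edge list (`gene_i`, `gene_j`, `r`, `sign`); `graphml`
#' writes a GraphML graph with `r` and `sign` edge attributes (via igraph).
#' Both round-trip through [read_network()].
#'
#' @param network a [build_network()] result.
#' @param path output file.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(network$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("gene_i", "gene_j", "r", "sign")],
      directed = FALSE,
      vertices = data.frame(name = network$nodes))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import an exported network edge list
#'
#' @param path file written by [export_network()].
#' @param format `"tsv"` or `"graphml"`.
#' @param pos_cut,neg_cut thresholds recorded on the rebuilt object.
#' @return A `correlation_network`.
#' @export
read_network <- function(path, format = c("tsv", "graphml"),
                         pos_cut = NA, neg_cut = NA) {
  format <- match.arg(format)
  if (format == "tsv") {
    edges <- read.table(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE,
                        colClasses = c("character", "character",
                                       "numeric", "character"))
    nodes <- sort(unique(c(edges$gene_i, edges$gene_j)))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    nodes <- igraph::V(g)$name
    edges <- data.frame(gene_i = el$from, gene_j = el$to,
                        r = el$r, sign = el$sign, stringsAsFactors = FALSE)
  }
  swap <- edges$gene_i > edges$gene_j
  tmp <- edges$gene_i[swap]
  edges$gene_i[swap] <- edges$gene_j[swap]
  edges$gene_j[swap] <- tmp
  edges <- edges[order(edges$gene_i, edges$gene_j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 pos_cut = pos_cut, neg_cut = neg_cut),
            class = "correlation_network")
}
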