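#' Construct a CMA gene network
#'
#' A CMA network is the scored gene set behind the transcriptional CMA score:
#' each component gene carries a positive weight \eqn{w_i} (LAMP2A, the
#' rate-limiting CMA receptor, is conventionally given weight 2 and all other
#' components weight 1) and a direction \eqn{d_i \in \{+1, -1\}} encoding
#' whether the gene promotes (+1) or represses (-1) CMA activity.
#'
#' @param gene character vector of gene symbols; normalised to upper case so
#'   human/mouse symbol-case differences cannot break matching.
#' @param weight positive numeric weights, recycled to `length(gene)`.
#' @param direction integer directions, each exactly `+1` or `-1`, recycled.
#' @param name short label for the network.
#' @param provenance free-text citation or description of where the gene list
#'   came from.
#' @return An object of class `cma_network`: a data frame with columns
#'   `gene`, `weight`, `direction` and attributes `name` and `provenance`.
#' @examples
#' net <- cma_network(c("LAMP2A", "HSPA8", "GFAP"),
#'                    weight = c(2, 1, 1), direction = c(1, 1, -1))
#' net
#' @seealso [read_cma_network()], [cma_score()]
#' @export
cma_network <- function(gene, weight = 1, direction = 1,
                        name = "cma_network", provenance = "") {
  if (length(gene) < 1L) stop_input("a CMA network needs at least one gene")
  gene <- toupper(trimws(as.character(gene)))
  n <- length(gene)
  weight <- rep_len(as.numeric(weight), n)
  direction <- rep_len(as.numeric(direction), n)
  for (i in seq_len(n)) {
    if (is.na(gene[i]) || !nzchar(gene[i])) {
      stop_input("row ", i, ": empty gene symbol")
    }
    if (!is.finite(weight[i]) || weight[i] <= 0) {
      stop_input("row ", i, " (", gene[i], "): weight must be a positive number, got ",
                 weight[i])
    }
    if (!is.finite(direction[i]) || !direction[i] %in% c(-1, 1)) {
      stop_input("row ", i, " (", gene[i], "): direction must be +1 or -1, got ",
                 direction[i])
    }
  }
  dup <- unique(gene[duplicated(gene)])
  if (length(dup)) stop_input("duplicate gene(s) in network: ", paste(dup, collapse = ", "))
  out <- data.frame(gene = gene, weight = weight, direction = as.integer(direction),
                    stringsAsFactors = FALSE)
  attr(out, "name") <- as.character(name)
  attr(out, "provenance") <- as.character(provenance)
  class(out) <- c("cma_network", "data.frame")
  out
}

#' @export
print.cma_network <- function(x, ...) {
  cat("CMA network '", attr(x, "name"), "': ", nrow(x), " genes (",
      sum(x$direction == 1L), " activating, ", sum(x$direction == -1L),
      " repressing), total weight ", sum(x$weight), "\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read a CMA network from a TSV or YAML file
#'
#' TSV files must have header columns `gene`, `weight`, `direction`
#' (lines starting with `#` are ignored).  YAML files carry the same fields
#' as a `components` list plus optional `name` and `provenance`.  Validation
#' errors name the offending row.
#'
#' @param path path to a `.tsv`/`.txt` or `.yaml`/`.yml` network file.
#' @return A validated [cma_network()].
#' @examples
#' path <- system.file("extdata", "cma_network_example.tsv", package = "cmaflux")
#' read_cma_network(path)
#' @export
read_cma_network <- function(path) {
  if (!is.character(path) || length(path) != 1L) stop_input("network path must be a single string")
  if (!file.exists(path)) stop_input("network file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    comp <- y$components %||% stop_input("YAML network must have a 'components' list: ", path)
    if (!length(comp)) stop_input("network file has no components: ", path)
    genes <- vapply(comp, function(cp) as.character(cp$gene %||% ""), character(1))
    weights <- vapply(comp, function(cp) as.numeric(cp$weight %||% NA_real_), numeric(1))
    dirs <- vapply(comp, function(cp) as.numeric(cp$direction %||% NA_real_), numeric(1))
    return(cma_network(genes, weights, dirs,
                       name = y$name %||% basename(path),
                       provenance = y$provenance %||% ""))
  }
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("gene", "weight", "direction")
  if (!all(need %in% names(df))) {
    stop_input("network TSV must have columns gene, weight, direction: ", path)
  }
  if (nrow(df) == 0L) stop_input("network file has no components: ", path)
  w <- suppressWarnings(as.numeric(df$weight))
  d <- suppressWarnings(as.numeric(df$direction))
  bad <- which(is.na(w) | is.na(d))
  if (length(bad)) {
    stop_input("row ", bad[1L], " (", df$gene[bad[1L]],
               "): non-numeric weight or direction")
  }
  cma_network(df$gene, w, d, name = basename(path), provenance = path)
}

#' Write a CMA network to a TSV or YAML file
#'
#' @param net a [cma_network()].
#' @param path output path; a `.yaml`/`.yml` extension selects YAML,
#'   anything else TSV.
#' @return `path`, invisibly.
#' @export
write_cma_network <- function(net, path) {
  net <- as_cma_network(net)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- list(
      name = attr(net, "name"),
      provenance = attr(net, "provenance"),
      components = lapply(seq_len(nrow(net)), function(i) {
        list(gene = net$gene[i], weight = net$weight[i],
             direction = net$direction[i])
      })
    )
    yaml::write_yaml(y, path, precision = 15L)
  } else {
    write_tsv(as.data.frame(net)[, c("gene", "weight", "direction")], path)
  }
  invisible(path)
}

as_cma_network <- function(net) {
  if (inherits(net, "cma_network")) return(net)
  if (is.data.frame(net) && all(c("gene", "weight", "direction") %in% names(net))) {
    return(cma_network(net$gene, net$weight, net$direction))
  }
  stop_input("'net' must be a cma_network or a data frame with gene/weight/direction")
}

#' Check which network genes an expression matrix covers
#'
#' Partitions the network's genes into those present among the matrix rows
#' (matched case-insensitively) and those missing.  Absence is reported, not
#' fatal: scoring renormalises over present genes by default.
#'
#' @param net a [cma_network()].
#' @param expr a gene-by-sample numeric matrix with gene symbols as rownames,
#'   or anything accepted by `rownames()`.
#' @return A list with character vectors `present` and `missing` (network
#'   symbols, upper case) and `coverage`, the fraction present.
#' @export
network_coverage <- function(net, expr) {
  net <- as_cma_network(net)
  rows <- toupper(rownames(expr) %||% character(0))
  present <- net$gene[net$gene %in% rows]
  list(present = present,
       missing = setdiff(net$gene, present),
       coverage = length(present) / nrow(net))
}
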