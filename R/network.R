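# Weighted-network container and plain-text edge-list I/O.
#
# A `weighted_network` is a tibble of links (source, target, weight) with
# attributes: `directed`, `weight_kind` ("integer"/"real") and `nodes` (the
# full node set, including explicitly declared isolated nodes). Node
# identifiers are case-sensitive opaque strings.

#' Construct a weighted network from a link table
#'
#' Validates and classes a table of links. Weights must be strictly
#' positive (zero or absent means no link), self-loops are rejected, and
#' duplicate links are an error rather than silently aggregated. For
#' undirected networks a pair present in both orientations with equal
#' weights is stored once; unequal weights are a conflict.
#'
#' @param links A data frame with columns `source`, `target`, `weight`
#'   (or any three columns in that order).
#' @param directed Logical; are links directed?
#' @param nodes Optional character vector of node identifiers; defaults to
#'   the link endpoints. Extra names declare isolated nodes.
#' @return A `weighted_network`: a tibble of links with attributes
#'   `directed`, `weight_kind` and `nodes`.
#' @examples
#' net <- weighted_network(
#'   data.frame(source = "A", target = c("B", "C", "D"), weight = c(2, 1, 1))
#' )
#' @export
weighted_network <- function(links, directed = FALSE, nodes = NULL) {
  if (inherits(links, "weighted_network") && is.null(nodes)) {
    links <- as.data.frame(links)[, c("source", "target", "weight")]
  }
  if (!is.data.frame(links)) {
    abort("`links` must be a data frame.", class = "polya_format_error")
  }
  if (ncol(links) < 3L) {
    abort("`links` needs columns source, target, weight.", class = "polya_format_error")
  }
  lk <- tibble::tibble(
    source = as.character(links[[if ("source" %in% names(links)) "source" else 1L]]),
    target = as.character(links[[if ("target" %in% names(links)) "target" else 2L]]),
    weight = as.numeric(links[[if ("weight" %in% names(links)) "weight" else 3L]])
  )
  validate_links(lk, directed, line = NULL)
  if (!directed) lk <- collapse_undirected(lk)
  node_set <- unique(c(lk$source, lk$target))
  if (!is.null(nodes)) node_set <- unique(c(as.character(nodes), node_set))
  new_weighted_network(lk, directed = directed, nodes = node_set)
}

new_weighted_network <- function(lk, directed, nodes) {
  kind <- if (nrow(lk) == 0L || all(is_wholenumber(lk$weight))) "integer" else "real"
  structure(
    tibble::new_tibble(lk, nrow = nrow(lk)),
    directed = directed,
    weight_kind = kind,
    nodes = nodes,
    class = c("weighted_network", class(tibble::tibble()))
  )
}

fmt_line <- function(line, i) {
  if (is.null(line)) sprintf("row %d", i) else sprintf("line %d", line[i])
}

validate_links <- function(lk, directed, line = NULL) {
  bad <- which(!is.finite(lk$weight) | lk$weight <= 0)
  if (length(bad)) {
    abort(sprintf("non-positive or missing weight at %s.", fmt_line(line, bad[1])),
          class = "polya_format_error")
  }
  loops <- which(lk$source == lk$target)
  if (length(loops)) {
    abort(sprintf("self-loop at %s.", fmt_line(line, loops[1])),
          class = "polya_format_error")
  }
  key <- if (directed) {
    paste(lk$source, lk$target, sep = "\r")
  } else {
    paste(pmin(lk$source, lk$target), pmax(lk$source, lk$target), sep = "\r")
  }
  dup <- which(duplicated(key))
  if (length(dup)) {
    if (directed) {
      abort(sprintf("duplicate link at %s.", fmt_line(line, dup[1])),
            class = "polya_format_error")
    }
    for (i in dup) {
      first <- match(key[i], key)
      if (lk$source[first] == lk$source[i]) {
        abort(sprintf("duplicate link at %s.", fmt_line(line, i)),
              class = "polya_format_error")
      }
      if (!isTRUE(all.equal(lk$weight[first], lk$weight[i]))) {
        abort(sprintf("duplicate link with conflicting weight at %s.",
                      fmt_line(line, i)),
              class = "polya_format_error")
      }
    }
  }
  invisible(lk)
}

# keep one row per unordered pair (weights already checked equal)
collapse_undirected <- function(lk) {
  key <- paste(pmin(lk$source, lk$target), pmax(lk$source, lk$target), sep = "\r")
  lk[!duplicated(key), , drop = FALSE]
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("# A weighted_network: %d nodes, %d links (%s, %s weights)\n",
              length(attr(x, "nodes")), nrow(x),
              if (attr(x, "directed")) "directed" else "undirected",
              attr(x, "weight_kind")))
  NextMethod()
}

net_directed <- function(net) isTRUE(attr(net, "directed"))
net_nodes <- function(net) attr(net, "nodes") %||% unique(c(net$source, net$target))
net_weight_kind <- function(net) {
  attr(net, "weight_kind") %||%
    (if (all(is_wholenumber(net$weight))) "integer" else "real")
}

as_weighted_network <- function(net, directed = NULL) {
  if (inherits(net, "weighted_network")) return(net)
  weighted_network(net, directed = isTRUE(directed))
}

#' Read a weighted edge list from delimited text
#'
#' Reads a plain-text edge list with columns source, target, weight.
#' The delimiter (tab, comma, or runs of whitespace) is sniffed from the
#' first data line; `#` lines are comments and an optional header row is
#' detected by a non-numeric third field. A data line with a single field
#' declares an isolated node. For undirected input, a pair listed in both
#' orientations must carry equal weights and is stored once.
#'
#' @param path Path to the file.
#' @param directed Logical; interpret rows as directed links?
#' @return A [weighted_network()] with `weight_kind` auto-detected.
#' @export
read_edgelist <- function(path, directed = FALSE) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    return(new_weighted_network(
      tibble::tibble(source = character(), target = character(), weight = numeric()),
      directed = directed, nodes = character()
    ))
  }
  sniff <- lines[1]
  split_fields <- if (grepl("\t", sniff)) {
    function(x) strsplit(x, "\t", fixed = TRUE)
  } else if (grepl(",", sniff)) {
    function(x) strsplit(x, ",", fixed = TRUE)
  } else {
    function(x) strsplit(trimws(x), "\\s+")
  }
  fields <- lapply(split_fields(lines), trimws)
  # header: first row whose third field is not numeric
  first <- fields[[1]]
  if (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3])))) {
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  if (length(fields) == 0L) {
    return(new_weighted_network(
      tibble::tibble(source = character(), target = character(), weight = numeric()),
      directed = directed, nodes = character()
    ))
  }
  nf <- lengths(fields)
  iso <- nf == 1L
  bad <- which(!iso & nf < 3L)
  if (length(bad)) {
    abort(sprintf("malformed row at line %d: expected source, target, weight.",
                  line_no[bad[1]]),
          class = "polya_format_error")
  }
  iso_nodes <- vapply(fields[iso], `[[`, character(1), 1L)
  fields <- fields[!iso]
  dline <- line_no[!iso]
  if (length(fields) == 0L) {
    return(new_weighted_network(
      tibble::tibble(source = character(), target = character(), weight = numeric()),
      directed = directed, nodes = unique(iso_nodes)
    ))
  }
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  nonnum <- which(is.na(w))
  if (length(nonnum)) {
    abort(sprintf("non-numeric weight at line %d.", dline[nonnum[1]]),
          class = "polya_format_error")
  }
  lk <- tibble::tibble(
    source = vapply(fields, `[[`, character(1), 1L),
    target = vapply(fields, `[[`, character(1), 2L),
    weight = w
  )
  validate_links(lk, directed, line = dline)
  if (!directed) lk <- collapse_undirected(lk)
  new_weighted_network(lk, directed = directed,
                       nodes = unique(c(iso_nodes, lk$source, lk$target)))
}

#' Per-node degree and strength table
#'
#' Degree `k` counts a node's links with positive weight; strength `s` sums
#' their weights. Directed networks report out- and in-variants separately.
#' Isolated nodes appear with zeros.
#'
#' @param net A [weighted_network()] or coercible data frame.
#' @param directed Directedness override when `net` is a bare data frame.
#' @return A tibble with one row per node: `node`, `k`, `s` (undirected) or
#'   `node`, `k_out`, `s_out`, `k_in`, `s_in` (directed).
#' @examples
#' node_stats(fig1_fixture()) # node A: k = 3, s = 4
#' @export
node_stats <- function(net, directed = NULL) {
  net <- as_weighted_network(net, directed)
  nodes <- net_nodes(net)
  if (net_directed(net)) {
    out <- dplyr::summarise(dplyr::group_by(net, node = .data$source),
                            k_out = dplyr::n(), s_out = sum(.data$weight))
    inn <- dplyr::summarise(dplyr::group_by(net, node = .data$target),
                            k_in = dplyr::n(), s_in = sum(.data$weight))
    res <- tibble::tibble(node = nodes) |>
      dplyr::left_join(out, by = "node") |>
      dplyr::left_join(inn, by = "node") |>
      dplyr::mutate(dplyr::across(-"node", \(x) dplyr::coalesce(x, 0)))
  } else {
    long <- tibble::tibble(node = c(net$source, net$target),
                           weight = c(net$weight, net$weight))
    agg <- dplyr::summarise(dplyr::group_by(long, .data$node),
                            k = dplyr::n(), s = sum(.data$weight))
    res <- tibble::tibble(node = nodes) |>
      dplyr::left_join(agg, by = "node") |>
      dplyr::mutate(dplyr::across(-"node", \(x) dplyr::coalesce(x, 0)))
  }
  res
}

#' Write a backbone to delimited text
#'
#' Writes tab-delimited columns `source`, `target`, `weight`,
#' `p_value_min`, preceded by `#` comment lines recording the filter
#' settings (`a`, `alpha_u`, `correction`, `L`). Re-reading the file with
#' [read_edgelist()] reproduces the retained link set and weights.
#'
#' @param b A backbone from [extract_backbone()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_backbone <- function(b, path) {
  stopifnot(inherits(b, "polya_backbone"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot open '%s' for writing.", path), class = "polya_io_error")
  })
  on.exit(close(con))
  writeLines(c(
    "# polyafilter backbone",
    sprintf("# a=%.10g alpha_u=%.10g correction=%s L=%d directed=%s",
            b$a, b$alpha_u, b$correction, b$L, b$directed),
    "source\ttarget\tweight\tp_value_min"
  ), con)
  if (nrow(b$links)) {
    writeLines(sprintf("%s\t%s\t%.10g\t%.10g",
                       b$links$source, b$links$target,
                       b$links$weight, b$links$p_value_min), con)
  }
  invisible(path)
}
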