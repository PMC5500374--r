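# Instance file input/output (self-describing JSON schema) and graph
# exports (DOT, GraphML) in the style of the model's figures: nodes
# and edges labeled with Q-block/R-block composition strings, active
# molecules marked.

#' Read and write network instances
#'
#' Instances are stored as self-describing JSON: `molecules`,
#' `compartments` (id + composition string), `edges` (source, target,
#' composition string), `pairing` (M x M 0/1 rows), `regime`
#' (compartment/vesicle rules) and optional `regulation` maps from
#' composition strings to activity strings per side. Composition
#' strings are Q-block then R-block (space optional on input, emitted
#' without a space). `read_instance(write_instance(x))` is the
#' identity.
#'
#' @param path file path.
#' @return a [network_instance()].
#' @export
read_instance <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fail <- function(where, msg) stop("schema error at ", where, ": ", msg)
  if (is.null(j$molecules)) fail("/molecules", "missing")
  M <- as.integer(j$molecules)
  if (is.na(M) || M < 2 || M %% 2 != 0) fail("/molecules", "must be even >= 2")
  uni <- molecule_universe(M)
  parse_comp <- function(s, where) {
    out <- tryCatch(comp_from_string(s, M), error = function(e) NULL)
    if (is.null(out)) fail(where, paste0("bad composition string '", s, "'"))
    out
  }
  if (is.null(j$compartments)) fail("/compartments", "missing")
  comps <- list()
  for (i in seq_along(j$compartments)) {
    c0 <- j$compartments[[i]]
    if (is.null(c0$id)) fail(paste0("/compartments/", i), "missing id")
    comps[[as.character(c0$id)]] <-
      parse_comp(c0$composition, paste0("/compartments/", i, "/composition"))
  }
  edges <- list()
  for (i in seq_along(j$edges)) {
    e0 <- j$edges[[i]]
    if (is.null(e0$source) || is.null(e0$target))
      fail(paste0("/edges/", i), "missing source/target")
    edges[[i]] <- vesicle_edge(e0$source, e0$target,
      parse_comp(e0$composition, paste0("/edges/", i, "/composition")))
  }
  if (is.null(j$pairing)) fail("/pairing", "missing")
  pm <- do.call(rbind, lapply(j$pairing, function(r) as.integer(unlist(r))))
  if (!all(dim(pm) == c(M, M))) fail("/pairing", "must be an MxM matrix")
  pairing <- tryCatch(pairing_matrix(pm, uni),
                      error = function(e) fail("/pairing", conditionMessage(e)))
  if (is.null(j$regime)) fail("/regime", "missing")
  regime <- tryCatch(
    regulation_regime(j$regime$compartment, j$regime$vesicle),
    error = function(e) fail("/regime", conditionMessage(e)))
  reg <- NULL
  if (!is.null(j$regulation)) {
    conv <- function(side) {
      m0 <- j$regulation[[side]]
      if (is.null(m0)) return(NULL)
      out <- vapply(m0, function(x) gsub(" ", "", as.character(x)), "")
      names(out) <- gsub(" ", "", names(m0))
      out
    }
    reg <- regulation_function(compartment = conv("compartment"),
                               vesicle = conv("vesicle"))
  }
  network_instance(transport_network(uni, comps, edges), pairing, regime, reg)
}

#' @rdname read_instance
#' @param instance a [network_instance()].
#' @export
write_instance <- function(instance, path) {
  net <- instance$network
  M <- net$universe$M
  j <- list(
    molecules = M,
    compartments = lapply(seq_along(net$node_ids), function(i)
      list(id = net$node_ids[i],
           composition = comp_to_string(net$node_comp[i, ], space = FALSE))),
    edges = lapply(seq_along(net$edge_src), function(i)
      list(source = net$edge_src[i], target = net$edge_tgt[i],
           composition = comp_to_string(net$edge_comp[i, ], space = FALSE))),
    pairing = lapply(seq_len(M), function(i) as.integer(instance$pairing[i, ])),
    regime = list(compartment = instance$regime$compartment_rule,
                  vesicle = instance$regime$vesicle_rule))
  if (!is.null(instance$regulation)) {
    r <- list()
    if (!is.null(instance$regulation$compartment))
      r$compartment <- as.list(instance$regulation$compartment)
    if (!is.null(instance$regulation$vesicle))
      r$vesicle <- as.list(instance$regulation$vesicle)
    j$regulation <- r
  }
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export a network instance as DOT or GraphML
#'
#' Nodes are labeled with their composition strings (Q-block then
#' R-block), edges with theirs; active molecules (per the instance's
#' regime and regulation) are listed separately on each label.
#'
#' @param instance a [network_instance()].
#' @param path output file.
#' @param format `"dot"` or `"graphml"`.
#' @export
export_graph <- function(instance, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  net <- instance$network
  act_str <- function(a) {
    idx <- which(a == 1L)
    if (!length(idx)) return("-")
    h <- net$universe$M %/% 2
    paste(ifelse(idx <= h, paste0("Q", idx - 1L), paste0("R", idx - h - 1L)),
          collapse = ",")
  }
  node_lab <- vapply(seq_along(net$node_ids), function(i) sprintf(
    "%s [%s] act:%s", net$node_ids[i], comp_to_string(net$node_comp[i, ]),
    act_str(instance_node_active(instance, net$node_ids[i]))), "")
  edge_lab <- vapply(seq_along(net$edge_src), function(i) sprintf(
    "[%s] act:%s", comp_to_string(net$edge_comp[i, ]),
    act_str(instance_edge_active(instance, i))), "")
  if (format == "dot") {
    lines <- c("digraph vesicle_traffic {",
               sprintf('  "%s" [label="%s"];', net$node_ids, node_lab))
    for (i in seq_along(net$edge_src))
      lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];',
                                net$edge_src[i], net$edge_tgt[i], edge_lab[i]))
    lines <- c(lines, "}")
    writeLines(lines, path)
  } else {
    esc <- function(s) gsub("<", "&lt;", gsub("&", "&amp;", s))
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns"',
      '  xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance"',
      '  xsi:schemaLocation="http://graphml.graphdrawing.org/xmlns http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd">',
      '  <key id="label" for="all" attr.name="label" attr.type="string"/>',
      '  <graph id="G" edgedefault="directed">')
    for (i in seq_along(net$node_ids))
      lines <- c(lines, sprintf(
        '    <node id="%s"><data key="label">%s</data></node>',
        net$node_ids[i], esc(node_lab[i])))
    for (i in seq_along(net$edge_src))
      lines <- c(lines, sprintf(
        '    <edge id="e%d" source="%s" target="%s"><data key="label">%s</data></edge>',
        i, net$edge_src[i], net$edge_tgt[i], esc(edge_lab[i])))
    lines <- c(lines, "  </graph>", "</graphml>")
    writeLines(lines, path)
  }
  invisible(path)
}
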