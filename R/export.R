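# Serialization of fragmentation and consensus trees: a JSON document with
# full node records, and a compact Chemical Markup Language (CML) subset
# combining the chemical (elemental formula) and the mass-spectrometric
# (m/z, relative intensity) record of each ion. The CML subset is
# self-defined; its XSD ships under inst/schema/.

#' Export a fragmentation or consensus tree as JSON
#'
#' Full node records (EFP, formula, observed and theoretical m/z, relative
#' intensity, ppm error, ambiguity flag) plus the constraint snapshot.
#' Output is deterministic: identical trees yield byte-identical files.
#'
#' @param x a `fragmentation_tree` or `consensus_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_json <- function(x, path) {
  doc <- if (inherits(x, "fragmentation_tree")) {
    list(type = "fragmentation_tree", root = x$root_token,
         polarity = x$polarity, compound_id = x$compound_id,
         params = list(tol_ppm = x$constraints$tol_ppm,
                       element_max = as.list(x$constraints$element_max),
                       ratio_rules_enabled = x$constraints$ratio_rules_enabled,
                       rdbe_rule = x$constraints$rdbe_rule),
         nodes = x$nodes)
  } else if (inherits(x, "consensus_tree")) {
    list(type = "consensus_tree", root = x$root_token,
         n_repetitions = x$n_repetitions, min_fraction = x$min_fraction,
         entries = x$entries)
  } else {
    stop("export_json() handles fragmentation_tree or consensus_tree", call. = FALSE)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Import a tree exported by [export_json()]
#'
#' @param path JSON file path.
#' @return a `fragmentation_tree` or `consensus_tree`.
#' @export
import_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$type, "fragmentation_tree")) {
    cons <- formula_constraints(
      tol_ppm = doc$params$tol_ppm,
      element_max = unlist(doc$params$element_max),
      ratio_rules_enabled = doc$params$ratio_rules_enabled,
      rdbe_rule = doc$params$rdbe_rule
    )
    nodes <- as.data.frame(doc$nodes, stringsAsFactors = FALSE)
    out <- structure(
      list(nodes = nodes, root_token = doc$root, polarity = doc$polarity,
           compound_id = doc$compound_id, constraints = cons, log = character()),
      class = "fragmentation_tree"
    )
    return(validate_fragmentation_tree(out))
  }
  if (identical(doc$type, "consensus_tree")) {
    return(structure(
      list(entries = as.data.frame(doc$entries, stringsAsFactors = FALSE),
           n_repetitions = doc$n_repetitions, root_token = doc$root,
           min_fraction = doc$min_fraction),
      class = "consensus_tree"
    ))
  }
  stop("unrecognized tree JSON (missing/unknown $type)", call. = FALSE)
}

#' Export a tree in the package's CML subset
#'
#' One `molecule` element per ion (with its display-dialect formula and the
#' EFP as id), one `spectrum` element per MS level, and parent-child links
#' by id reference. Intensities and m/z live on `peak` elements inside each
#' spectrum. Full CML conformance is not claimed; the subset schema is
#' documented in `inst/schema/fragtree-cml.xsd`.
#'
#' @param x a `fragmentation_tree` or `consensus_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_cml <- function(x, path) {
  if (inherits(x, "fragmentation_tree")) {
    nodes <- x$nodes
    intens <- nodes$rel_intensity
    root <- x$root_token
  } else if (inherits(x, "consensus_tree")) {
    nodes <- x$entries
    nodes$token <- vapply(strsplit(nodes$efp, "||", fixed = TRUE),
                          function(p) p[length(p)], character(1))
    nodes$display <- vapply(nodes$token,
                            function(t) serialize_formula(parse_formula(t)), character(1))
    nodes$observed_mz <- NA_real_
    intens <- nodes$mean_rel_intensity
    root <- x$root_token
  } else {
    stop("export_cml() handles fragmentation_tree or consensus_tree", call. = FALSE)
  }
  doc <- xml2::xml_new_root("cml", xmlns = "http://www.xml-cml.org/schema")
  xml2::xml_set_attr(doc, "convention", "fragtree:fragmentationTree")
  xml2::xml_set_attr(doc, "title", root)
  mol_list <- xml2::xml_add_child(doc, "moleculeList")
  ids <- paste0("ion", seq_len(nrow(nodes)))
  names(ids) <- nodes$efp
  for (i in seq_len(nrow(nodes))) {
    parts <- strsplit(nodes$efp[i], "||", fixed = TRUE)[[1]]
    parent <- if (length(parts) > 1L) {
      paste(parts[-length(parts)], collapse = "||")
    } else NA_character_
    mol <- xml2::xml_add_child(mol_list, "molecule")
    xml2::xml_set_attr(mol, "id", ids[[nodes$efp[i]]])
    xml2::xml_set_attr(mol, "formalCharge", "1")
    xml2::xml_set_attr(mol, "formula", nodes$display[i])
    xml2::xml_set_attr(mol, "ref", nodes$efp[i])
    if (!is.na(parent) && parent %in% names(ids)) {
      xml2::xml_set_attr(mol, "parentRef", ids[[parent]])
    }
  }
  spec_list <- xml2::xml_add_child(doc, "spectrumList")
  for (lvl in sort(unique(nodes$ms_level))) {
    sel <- which(nodes$ms_level == lvl)
    sp <- xml2::xml_add_child(spec_list, "spectrum")
    xml2::xml_set_attr(sp, "id", paste0("ms", lvl))
    xml2::xml_set_attr(sp, "type", "massSpectrum")
    pl <- xml2::xml_add_child(sp, "peakList")
    for (i in sel) {
      pk <- xml2::xml_add_child(pl, "peak")
      xml2::xml_set_attr(pk, "moleculeRefs", ids[[nodes$efp[i]]])
      if (!is.na(nodes$observed_mz[i])) {
        xml2::xml_set_attr(pk, "xValue", format(nodes$observed_mz[i], digits = 10))
      }
      xml2::xml_set_attr(pk, "yValue", format(intens[i], digits = 10))
      xml2::xml_set_attr(pk, "xUnits", "unit:mz")
      xml2::xml_set_attr(pk, "yUnits", "unit:relativeIntensity")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
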