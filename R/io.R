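#' Read a metabolic network from a file
#'
#' Two dialects are supported. `"sbml"` parses SBML Level 2 or Level 3
#' (species: `id`, `name`, `boundaryCondition`; reactions: `reversible`,
#' `listOfReactants`/`listOfProducts` with `stoichiometry`, defaulting to 1
#' when the attribute is absent). `"idlist"` parses a plain-text file with one
#' metabolite id per line (`#` comments and blank lines ignored) and yields a
#' network of isolated metabolites, the format used for seeds and targets
#' files.
#'
#' @param path Path to an existing file.
#' @param dialect `"sbml"` (default) or `"idlist"`.
#' @return A `gs_network`.
#' @seealso [write_network()]
#' @export
read_network <- function(path, dialect = c("sbml", "idlist")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "idlist") read_idlist(path) else read_sbml(path)
}

read_idlist <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  ids <- unique(lines[nzchar(lines)])
  met_network(list(), metabolites = ids)
}

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  doc <- xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) {
    stop("SBML parse error in '", path, "': no <model> element", call. = FALSE)
  }
  level <- xml2::xml_attr(doc, "level")
  if (!is.na(level) && !(level %in% c("2", "3"))) {
    stop("unsupported SBML level '", level, "' in '", path, "'", call. = FALSE)
  }

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    boundary = xml2::xml_attr(sp_nodes, "boundaryCondition") %in%
      c("true", "1"),
    stringsAsFactors = FALSE)
  if (any(is.na(mets$id))) {
    stop("species without id in '", path, "'", call. = FALSE)
  }

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    if (is.na(rid)) stop("reaction without id in '", path, "'", call. = FALSE)
    rev_attr <- xml2::xml_attr(node, "reversible")
    # SBML L2 default for 'reversible' is true; L3 requires it
    reversible <- if (is.na(rev_attr)) TRUE else rev_attr %in% c("true", "1")
    side <- function(which) {
      refs <- xml2::xml_find_all(
        node, sprintf("./%s/speciesReference", which))
      if (!length(refs)) return(stats::setNames(numeric(), character()))
      sp <- xml2::xml_attr(refs, "species")
      st <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry")))
      st[is.na(st)] <- 1
      missing <- setdiff(sp, mets$id)
      if (length(missing)) {
        stop("reaction '", rid, "' references undeclared species '",
             missing[[1]], "' in '", path, "'", call. = FALSE)
      }
      stats::setNames(st, sp)
    }
    reaction(rid, side("listOfReactants"), side("listOfProducts"),
             reversible = reversible,
             name = {
               nm <- xml2::xml_attr(node, "name")
               if (is.na(nm)) NULL else nm
             })
  })
  met_network(reactions, mets)
}

#' Write a metabolic network as SBML
#'
#' Emits SBML Level 2 Version 4 that [read_network()] inverts: ids,
#' coefficients, reversibility and boundary flags round-trip exactly. Output
#' is deterministic (byte-stable for a given network).
#'
#' @param net A `gs_network`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "gs_network"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  fmt_num <- function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           format(x, digits = 15, scientific = FALSE, trim = TRUE))
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level2/version4\" ",
           "level=\"2\" version=\"4\">"),
    "  <model id=\"model\">",
    "    <listOfSpecies>")
  m <- net$metabolites
  for (i in seq_len(nrow(m))) {
    nm <- if (is.na(m$name[i])) "" else sprintf(" name=\"%s\"", esc(m$name[i]))
    lines <- c(lines, sprintf(
      "      <species id=\"%s\"%s boundaryCondition=\"%s\"/>",
      esc(m$id[i]), nm, if (m$boundary[i]) "true" else "false"))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfReactions>")
  for (r in net$reactions) {
    nm <- if (is.null(r$name)) "" else sprintf(" name=\"%s\"", esc(r$name))
    lines <- c(lines, sprintf(
      "      <reaction id=\"%s\"%s reversible=\"%s\">",
      esc(r$id), nm, if (r$reversible) "true" else "false"))
    for (side in c("listOfReactants", "listOfProducts")) {
      v <- if (side == "listOfReactants") r$reactants else r$products
      if (length(v)) {
        lines <- c(lines, sprintf("        <%s>", side))
        for (j in seq_along(v)) {
          lines <- c(lines, sprintf(
            "          <speciesReference species=\"%s\" stoichiometry=\"%s\"/>",
            esc(names(v)[j]), fmt_num(v[[j]])))
        }
        lines <- c(lines, sprintf("        </%s>", side))
      }
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Serialize a completion result to JSON
#'
#' @param result A `gs_completion` as returned by
#'   [enumerate_minimal_completions()].
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
completion_to_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "gs_completion"))
  payload <- list(
    reconstructable = as.list(result$reconstructable),
    unreconstructable = as.list(result$unreconstructable),
    optimum_size = result$optimum_size,
    solutions = lapply(result$solutions, as.list),
    union = as.list(result$union),
    intersection = as.list(result$intersection),
    enumeration_truncated = result$enumeration_truncated)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
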