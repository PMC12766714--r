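#' SBML Level 3 + FBC input/output
#'
#' Models are exchanged as SBML Level 3 Version 1 documents with the Flux
#' Balance Constraints (fbc) version 2 package: flux bounds as shared
#' parameters, the biomass reaction as the active maximization objective,
#' and carbon/phosphorus content as `fbc:chemicalFormula`. Package-specific
#' structure that plain SBML cannot hold (metabolite roles, reaction tags,
#' the maintenance/oxygen/carbon-exchange designations) is carried in
#' SBML `<notes>` elements, which other FBC tools ignore; when notes are
#' absent the reader falls back to id conventions (`EX_` prefix =>
#' exchange, the active objective => biomass).
#'
#' @name sbml-io
NULL

.SBML_NS <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
              fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
.COMP_CODE <- c(cytosol = "c", extracellular = "e", pool = "p")

.fmt_num <- function(x) sprintf("%.17g", x)

.notes_block <- function(kv) {
  items <- vapply(names(kv), function(k)
    sprintf("        <p>%s: %s</p>", k, kv[[k]]), character(1))
  paste0("      <notes>\n      <body xmlns=\"http://www.w3.org/1999/xhtml\">\n",
         paste(items, collapse = "\n"),
         "\n      </body>\n      </notes>\n")
}

#' Write a model as SBML Level 3 + FBC
#'
#' @param model a `gem_model`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sbml <- function(model, path) {
  met <- model$metabolites; rxn <- model$reactions; S <- model$stoichiometry
  bounds <- sort(unique(c(rxn$lower_bound, rxn$upper_bound)))
  bid <- setNames(paste0("bnd_", seq_along(bounds)), .fmt_num(bounds))
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"", .SBML_NS[["s"]], "\" xmlns:fbc=\"",
           .SBML_NS[["fbc"]],
           "\" level=\"3\" version=\"1\" fbc:required=\"false\">"),
    sprintf("  <model id=\"%s\" fbc:strict=\"false\">", model$id),
    .notes_block(c(
      maintenance_reaction = model$maintenance_reaction,
      o2_exchange = model$o2_exchange %||% "",
      carbon_exchanges = paste(model$carbon_exchanges, collapse = ","),
      amino_acid_exchanges = paste(names(model$amino_acid_exchanges),
                                   unname(model$amino_acid_exchanges),
                                   sep = "=", collapse = ";"),
      atp_metabolite = model$atp_metabolite %||% "",
      o2_uptake_limit = .fmt_num(model$o2_uptake_limit))),
    "    <listOfCompartments>",
    sprintf("      <compartment id=\"%s\" constant=\"true\"/>",
            unique(.COMP_CODE[met$compartment])),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (i in seq_len(nrow(met))) {
    formula <- paste0("C", met$carbon_atoms[i], "P", met$phosphorus_atoms[i])
    lines <- c(lines, sprintf(
      paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
             "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
             "constant=\"false\" fbc:chemicalFormula=\"%s\">"),
      met$id[i], met$name[i], .COMP_CODE[[met$compartment[i]]], formula),
      .notes_block(c(role = met$role[i])),
      "      </species>")
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>",
             sprintf(paste0("      <parameter id=\"%s\" value=\"%s\"",
                            " constant=\"true\"/>"),
                     unname(bid), names(bid)),
             "    </listOfParameters>", "    <listOfReactions>")
  for (j in seq_len(nrow(rxn))) {
    lines <- c(lines, sprintf(
      paste0("      <reaction id=\"%s\" reversible=\"%s\" fast=\"false\" ",
             "fbc:lowerFluxBound=\"%s\" fbc:upperFluxBound=\"%s\">"),
      rxn$id[j], tolower(rxn$lower_bound[j] < 0),
      bid[[.fmt_num(rxn$lower_bound[j])]],
      bid[[.fmt_num(rxn$upper_bound[j])]]),
      .notes_block(c(tags = paste(rxn$tags[[j]], collapse = ","))))
    coef <- S[, j]
    nz <- which(coef != 0)
    reac <- nz[coef[nz] < 0]; prod <- nz[coef[nz] > 0]
    if (length(reac)) lines <- c(
      lines, "        <listOfReactants>",
      sprintf(paste0("          <speciesReference species=\"%s\" ",
                     "stoichiometry=\"%s\" constant=\"true\"/>"),
              met$id[reac], .fmt_num(-coef[reac])),
      "        </listOfReactants>")
    if (length(prod)) lines <- c(
      lines, "        <listOfProducts>",
      sprintf(paste0("          <speciesReference species=\"%s\" ",
                     "stoichiometry=\"%s\" constant=\"true\"/>"),
              met$id[prod], .fmt_num(coef[prod])),
      "        </listOfProducts>")
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>",
             "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
             "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
             "        <fbc:listOfFluxObjectives>",
             sprintf(paste0("          <fbc:fluxObjective fbc:reaction=",
                            "\"%s\" fbc:coefficient=\"1\"/>"),
                     model$biomass_reaction),
             "        </fbc:listOfFluxObjectives>",
             "      </fbc:objective>",
             "    </fbc:listOfObjectives>",
             "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

.parse_notes <- function(node) {
  ps <- xml2::xml_find_all(node, "./s:notes//*[local-name()='p']", .SBML_NS)
  out <- list()
  for (p in ps) {
    txt <- xml2::xml_text(p)
    m <- regmatches(txt, regexec("^\\s*([^:]+):\\s*(.*)$", txt))[[1]]
    if (length(m) == 3) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

.parse_formula <- function(f) {
  atoms <- c(C = 0, P = 0)
  if (is.na(f) || !nzchar(f)) return(atoms)
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    nn <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(nn)) as.integer(nn) else 1L
    if (el %in% names(atoms)) atoms[[el]] <- n
  }
  atoms
}

#' Read a model from SBML Level 3 + FBC
#'
#' Round-trips with [write_sbml()]: a model written and re-read compares
#' structurally equal. Files produced by other tools are accepted as long
#' as they carry FBC flux bounds and an active biomass objective; tags and
#' roles are then inferred from id conventions.
#'
#' @param path SBML file.
#' @return a `gem_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)  # malformed XML errors name the element/line
  ns <- .SBML_NS
  model_node <- xml2::xml_find_first(doc, "//s:model", ns)
  if (inherits(model_node, "xml_missing")) stop("no <model> element found")

  comp_nodes <- xml2::xml_find_all(doc, "//s:compartment", ns)
  comp_map <- setNames(names(.COMP_CODE), unname(.COMP_CODE))

  sp <- xml2::xml_find_all(doc, "//s:species", ns)
  if (!length(sp)) stop("no <species> elements found")
  met <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = unname(comp_map[xml2::xml_attr(sp, "compartment")]),
    stringsAsFactors = FALSE)
  if (anyNA(met$compartment))
    met$compartment[is.na(met$compartment)] <- "cytosol"
  formulas <- xml2::xml_attr(sp, "chemicalFormula")
  atoms <- t(vapply(formulas, .parse_formula, numeric(2)))
  met$carbon_atoms <- as.integer(atoms[, 1])
  met$phosphorus_atoms <- as.integer(atoms[, 2])
  met$role <- vapply(sp, function(nd)
    .parse_notes(nd)$role %||% "generic", character(1))

  pars <- xml2::xml_find_all(doc, "//s:parameter", ns)
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(doc, "//s:reaction", ns)
  if (!length(rx)) stop("no <reaction> elements found")
  rid <- xml2::xml_attr(rx, "id")
  lb <- unname(parval[xml2::xml_attr(rx, "lowerFluxBound")])
  ub <- unname(parval[xml2::xml_attr(rx, "upperFluxBound")])
  if (anyNA(lb) || anyNA(ub))
    stop("reaction without resolvable fbc flux bounds: ",
         rid[which(is.na(lb) | is.na(ub))[1]])

  S <- Matrix::Matrix(0, nrow(met), length(rid),
                      dimnames = list(met$id, rid), sparse = TRUE)
  tags <- vector("list", length(rid))
  for (j in seq_along(rx)) {
    for (sr in xml2::xml_find_all(rx[[j]],
                                  "./s:listOfReactants/s:speciesReference",
                                  ns)) {
      sid <- xml2::xml_attr(sr, "species")
      if (!sid %in% met$id)
        stop("reaction ", rid[j], " references unknown species ", sid)
      S[sid, j] <- S[sid, j] - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rx[[j]],
                                  "./s:listOfProducts/s:speciesReference",
                                  ns)) {
      sid <- xml2::xml_attr(sr, "species")
      if (!sid %in% met$id)
        stop("reaction ", rid[j], " references unknown species ", sid)
      S[sid, j] <- S[sid, j] + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    nt <- .parse_notes(rx[[j]])
    tags[[j]] <- if (!is.null(nt$tags))
      strsplit(nt$tags, ",")[[1]]
    else if (startsWith(rid[j], "EX_")) "exchange" else "internal"
  }

  obj <- xml2::xml_find_first(
    doc, "//fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(obj, "xml_missing"))
    stop("model has no biomass objective (fbc:fluxObjective missing)")
  biomass <- xml2::xml_attr(obj, "reaction")
  jb <- match(biomass, rid)
  if (is.na(jb)) stop("biomass objective references unknown reaction ",
                      biomass)
  if (!"biomass" %in% tags[[jb]]) tags[[jb]] <- c(tags[[jb]], "biomass")

  notes <- .parse_notes(model_node)
  maint <- notes$maintenance_reaction
  if (is.null(maint)) {
    jm <- which(vapply(tags, function(t) "maintenance" %in% t, logical(1)))
    if (!length(jm)) jm <- grep("^ATPM", rid)
    if (!length(jm)) stop("cannot identify a maintenance reaction")
    maint <- rid[jm[1]]
  }
  jm <- match(maint, rid)
  if (!"maintenance" %in% tags[[jm]]) tags[[jm]] <- c(tags[[jm]],
                                                      "maintenance")

  split_or_null <- function(x) if (is.null(x) || !nzchar(x)) character()
    else strsplit(x, ",")[[1]]
  aa_map <- character()
  if (!is.null(notes$amino_acid_exchanges) &&
      nzchar(notes$amino_acid_exchanges)) {
    kv <- strsplit(strsplit(notes$amino_acid_exchanges, ";")[[1]], "=")
    aa_map <- setNames(vapply(kv, `[[`, character(1), 2),
                       vapply(kv, `[[`, character(1), 1))
  }
  o2 <- notes$o2_exchange
  if (!is.null(o2) && !nzchar(o2)) o2 <- NULL

  reactions <- data.frame(id = rid, lower_bound = lb, upper_bound = ub,
                          stringsAsFactors = FALSE)
  reactions$tags <- tags
  gem_model(met, reactions, S,
            biomass_reaction = biomass, maintenance_reaction = maint,
            o2_exchange = o2,
            carbon_exchanges = split_or_null(notes$carbon_exchanges),
            amino_acid_exchanges = aa_map,
            atp_metabolite = if (!is.null(notes$atp_metabolite) &&
                                   nzchar(notes$atp_metabolite))
              notes$atp_metabolite else NULL,
            o2_uptake_limit = as.numeric(notes$o2_uptake_limit %||% -1000),
            id = xml2::xml_attr(model_node, "id") %||% "model")
}
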