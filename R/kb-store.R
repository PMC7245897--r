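#' UniProt-style annotation record
#'
#' A minimal offline image of a curated protein/gene entry: its
#' recommended name, alternative names, gene names, short names, free-text
#' functional annotation, and (optionally) taxonomy. Name lists are
#' deduplicated case-insensitively at construction.
#'
#' @param accession Stable record identifier (e.g. a UniProt accession).
#' @param recommended_name Non-empty primary name.
#' @param alternative_names,gene_names,short_names Character vectors
#'   (possibly empty) of additional names.
#' @param function_text Free-text functional annotation.
#' @param taxonomy Optional taxonomy string (not used lexically).
#' @return Object of class `kb_record`.
#' @export
kb_record <- function(accession, recommended_name,
                      alternative_names = character(0),
                      gene_names = character(0),
                      short_names = character(0),
                      function_text = "", taxonomy = NULL) {
  stopifnot(is.character(recommended_name), nzchar(recommended_name))
  dedup_ci <- function(x) x[!duplicated(tolower(x))]
  structure(list(accession = accession,
                 recommended_name = recommended_name,
                 alternative_names = dedup_ci(as.character(alternative_names)),
                 gene_names = dedup_ci(as.character(gene_names)),
                 short_names = dedup_ci(as.character(short_names)),
                 function_text = function_text,
                 taxonomy = taxonomy),
            class = "kb_record")
}

#' Collect all names of a record
#'
#' Returns the union of the recommended name, alternative names, gene
#' names and short names, deduplicated case-insensitively with original
#' casing preserved, in that fixed order. This is the name-expansion step
#' that precedes reaction lookup: every alias of an entity is used to
#' query the reaction models.
#'
#' @param record A [kb_record()].
#' @return Character vector of names.
#' @export
collect_names <- function(record) {
  stopifnot(inherits(record, "kb_record"))
  x <- c(record$recommended_name, record$alternative_names,
         record$gene_names, record$short_names)
  x[!duplicated(tolower(x))]
}

#' Normalize a name for index lookup
#'
#' Case-folds, strips surrounding whitespace and collapses internal runs
#' of whitespace. Matching is exact after normalization; no stemming or
#' fuzzy matching, so every hit is auditable.
#'
#' @param x Character vector of names.
#' @return Normalized character vector.
#' @export
normalize_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' A reaction: an id plus its participant species names
#' @param reaction_id Identifier.
#' @param participants Character vector of species names
#'   (reactants, products and modifiers pooled); must be non-empty.
#' @return Object of class `kb_reaction`.
#' @export
kb_reaction <- function(reaction_id, participants) {
  participants <- unique(as.character(participants))
  stopifnot(length(participants) >= 1L)
  structure(list(reaction_id = reaction_id, participants = participants),
            class = "kb_reaction")
}

#' A curated reaction model (the `listOfReactions` content of one SBML model)
#' @param model_id Identifier.
#' @param reactions List of [kb_reaction()]s.
#' @param curated Curation flag; only curated models are admitted to a
#'   [kb_store()].
#' @return Object of class `kb_reaction_model`.
#' @export
kb_reaction_model <- function(model_id, reactions = list(), curated = TRUE) {
  stopifnot(all(vapply(reactions, inherits, TRUE, "kb_reaction")))
  structure(list(model_id = model_id, curated = isTRUE(curated),
                 reactions = reactions),
            class = "kb_reaction_model")
}

#' Parse the reactions of an SBML model
#'
#' Reads only the `listOfReactions` subtree of an SBML (level 2 or 3)
#' file: one reaction per `<reaction>` element, whose participants are
#' the species references of its reactant, product and modifier lists,
#' resolved to the species `name` attribute (falling back to the species
#' `id` when no name is given). Everything else in the model — kinetics,
#' compartments, rules — is ignored. Modifiers are included because
#' catalysts and regulators interact with the reaction's substrates even
#' though they are not consumed.
#'
#' @param sbml_path Path to an SBML file.
#' @param model_id Model id; defaults to the SBML `<model>` id attribute
#'   or the file basename.
#' @param curated Curation flag to record on the model.
#' @return A [kb_reaction_model()]; a model without a `listOfReactions`
#'   yields zero reactions (not an error).
#' @export
parse_sbml_reactions <- function(sbml_path, model_id = NULL, curated = TRUE) {
  doc <- xml2::read_xml(sbml_path)   # malformed XML raises here
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (is.null(model_id)) {
    mid <- if (!inherits(model_node, "xml_missing")) {
      xml2::xml_attr(model_node, "id")
    } else NA_character_
    model_id <- if (!is.na(mid)) mid else sub("\\.(xml|sbml)$", "",
                                              basename(sbml_path))
  }
  # species id -> display name
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp, "id")
  sp_name <- xml2::xml_attr(sp, "name")
  sp_name[is.na(sp_name) | !nzchar(sp_name)] <- sp_id[is.na(sp_name) | !nzchar(sp_name)]
  names(sp_name) <- sp_id

  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  reactions <- list()
  for (rx in rx_nodes) {
    refs <- xml2::xml_find_all(rx, ".//*[local-name()='speciesReference' or local-name()='modifierSpeciesReference']")
    species <- xml2::xml_attr(refs, "species")
    species <- species[!is.na(species)]
    if (!length(species)) next
    nm <- ifelse(species %in% names(sp_name), sp_name[species], species)
    rid <- xml2::xml_attr(rx, "id")
    if (is.na(rid)) rid <- paste0("rx", length(reactions) + 1L)
    reactions[[length(reactions) + 1L]] <- kb_reaction(rid, unname(nm))
  }
  kb_reaction_model(model_id, reactions, curated = curated)
}

#' Build an offline knowledge store
#'
#' Couples annotation records with curated reaction models and maintains
#' a normalized-name index over every name of every record. Non-curated
#' models are refused.
#'
#' @param records List of [kb_record()]s.
#' @param models List of [kb_reaction_model()]s (curated only).
#' @return Object of class `kb_store`.
#' @export
kb_store <- function(records = list(), models = list()) {
  stopifnot(all(vapply(records, inherits, TRUE, "kb_record")),
            all(vapply(models, inherits, TRUE, "kb_reaction_model")))
  if (length(models) && !all(vapply(models, function(m) m$curated, TRUE))) {
    stop("only curated reaction models may be loaded into the store")
  }
  names(records) <- vapply(records, function(r) r$accession, "")
  index <- new.env(parent = emptyenv())
  for (r in records) {
    for (nm in normalize_name(collect_names(r))) {
      index[[nm]] <- unique(c(index[[nm]], r$accession))
    }
  }
  structure(list(records = records, name_index = index, models = models),
            class = "kb_store")
}

#' @export
print.kb_store <- function(x, ...) {
  nrx <- sum(vapply(x$models, function(m) length(m$reactions), 1L))
  cat(sprintf("<kb_store> %d records, %d curated models, %d reactions\n",
              length(x$records), length(x$models), nrx))
  invisible(x)
}

#' Look up annotation records by surface form
#'
#' Returns every record one of whose names matches the query after
#' normalization ([normalize_name()]). Multiple hits are all returned:
#' when several records match it is not decidable which annotation is the
#' right one, so downstream code combines them all. An unknown surface
#' yields an empty list.
#'
#' @param surface Entity surface string.
#' @param store A [kb_store()].
#' @return List of [kb_record()]s (possibly empty).
#' @export
lookup_records <- function(surface, store) {
  stopifnot(inherits(store, "kb_store"))
  key <- normalize_name(surface)
  acc <- store$name_index[[key]]
  if (is.null(acc)) return(list())
  unname(store$records[acc])
}

#' Entities related to a surface through reaction co-participation
#'
#' Expands the query to all names of all matching records, then scans
#' every reaction of every curated model: whenever a reaction's
#' participants intersect the name set, the remaining participants are
#' emitted. Results are deduplicated (case-insensitively) in
#' deterministic order: model order, then reaction order, then
#' participant order. Names of the query entity itself are never
#' returned. No matching record or no intersecting reaction gives an
#' empty result.
#'
#' @param entity_surface Entity surface string.
#' @param store A [kb_store()].
#' @return Character vector of related entity names (possibly empty).
#' @export
related_entities <- function(entity_surface, store) {
  recs <- lookup_records(entity_surface, store)
  if (!length(recs)) return(character(0))
  names_all <- unique(unlist(lapply(recs, collect_names)))
  keys <- normalize_name(names_all)
  out <- character(0)
  for (m in store$models) {
    for (rx in m$reactions) {
      pk <- normalize_name(rx$participants)
      if (any(pk %in% keys)) {
        out <- c(out, rx$participants[!pk %in% keys])
      }
    }
  }
  out[!duplicated(normalize_name(out))]
}

#' Serialize a knowledge store to JSON
#' @param store A [kb_store()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_kb_store <- function(store, path) {
  stopifnot(inherits(store, "kb_store"))
  obj <- list(
    records = lapply(unname(store$records), function(r) {
      r[c("accession", "recommended_name", "alternative_names",
          "gene_names", "short_names", "function_text", "taxonomy")]
    }),
    models = lapply(store$models, function(m) {
      list(model_id = m$model_id, curated = m$curated,
           reactions = lapply(m$reactions, function(rx) {
             list(reaction_id = rx$reaction_id,
                  participants = rx$participants)
           }))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Deserialize a knowledge store from JSON
#' @param path Path written by [write_kb_store()].
#' @return A [kb_store()].
#' @export
read_kb_store <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(x) unlist(lapply(x, as.character), use.names = FALSE)
  records <- lapply(obj$records, function(r) {
    kb_record(r$accession, r$recommended_name,
              alternative_names = chr(r$alternative_names),
              gene_names = chr(r$gene_names),
              short_names = chr(r$short_names),
              function_text = if (is.null(r$function_text)) "" else r$function_text,
              taxonomy = r$taxonomy)
  })
  models <- lapply(obj$models, function(m) {
    kb_reaction_model(m$model_id,
                      lapply(m$reactions, function(rx) {
                        kb_reaction(rx$reaction_id, chr(rx$participants))
                      }),
                      curated = isTRUE(m$curated))
  })
  kb_store(records, models)
}
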