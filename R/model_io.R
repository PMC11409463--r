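## Loading mesoscale models. Standard mmCIF places molecule instances via
## Biological Assembly Descriptions: _pdbx_struct_oper_list holds rigid
## operators, _pdbx_struct_assembly_gen pairs an operator expression such
## as "(1-60)" or "(1-12)(13-18)" with the chains it applies to. The
## YASARA PetWorld dialect instead packs many objects into one file,
## separated by atom_site.pdbx_PDB_model_num, with per-model names and
## declared instance counts in pdbx_model.* and a PDB_model_num column on
## the gen rows.

## van der Waals radii (Angstrom) used when no explicit radius is stored.
element_radius <- function(sym) {
  tab <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
           FE = 1.93, MG = 1.73, ZN = 1.39, CA = 2.31, "NA" = 2.27,
           K = 2.75, CL = 1.75)
  r <- tab[toupper(sym)]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Compose assembly operators from an mmCIF oper_expression
#'
#' Expressions are comma lists of operator ids or id ranges, optionally
#' grouped in parentheses; consecutive parenthesized terms multiply as a
#' Cartesian product with the LEFT term applied LAST, i.e. "(X)(Y)" means
#' the composition X . Y (PDB convention).
#'
#' @param expr expression text, e.g. `"1"`, `"1,2,5-8"`, `"(1-60)"`,
#'   `"(1-12)(13-18)"`
#' @param operators named list: operator id -> list(rotation 3x3,
#'   translation numeric(3))
#' @return list of composed operators, each `list(id, rotation,
#'   translation)`; `id` joins the factor ids with `"*"`
#' @export
parse_oper_expression <- function(expr, operators) {
  expr <- gsub("\\s", "", expr)
  if (nchar(expr) == 0) stop("empty oper_expression")
  terms <- if (grepl("(", expr, fixed = TRUE)) {
    m <- gregexpr("\\(([^)]*)\\)", expr)[[1]]
    if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(expr))
      stop("cannot parse oper_expression '", expr, "'")
    regmatches(expr, gregexpr("(?<=\\()[^)]*(?=\\))", expr, perl = TRUE))[[1]]
  } else expr
  expand <- function(term) {
    if (nchar(term) == 0) stop("empty term in oper_expression '", expr, "'")
    unlist(lapply(strsplit(term, ",", fixed = TRUE)[[1]], function(el) {
      if (grepl("^[^-]+-[^-]+$", el)) {
        ab <- strsplit(el, "-", fixed = TRUE)[[1]]
        a <- suppressWarnings(as.integer(ab[1])); b <- suppressWarnings(as.integer(ab[2]))
        if (is.na(a) || is.na(b)) stop("bad range '", el, "' in oper_expression")
        as.character(seq(a, b))
      } else el
    }))
  }
  id_lists <- lapply(terms, expand)
  for (ids in id_lists)
    for (id in ids)
      if (is.null(operators[[id]]))
        stop("oper_expression references unknown operator id '", id, "'")
  ## Cartesian product, leftmost factor outermost and applied last
  combos <- Reduce(function(acc, ids) {
    unlist(lapply(acc, function(a) lapply(ids, function(b) c(a, b))),
           recursive = FALSE)
  }, id_lists, accumulate = FALSE, init = list(character()))
  lapply(combos, function(ids) {
    R <- diag(3); t <- c(0, 0, 0)
    for (id in ids) {                     # left-to-right: result = O_l . O_r
      op <- operators[[id]]
      t <- as.numeric(R %*% op$translation) + t
      R <- R %*% op$rotation
    }
    list(id = paste(ids, collapse = "*"), rotation = R, translation = t)
  })
}

## Read _pdbx_struct_oper_list into a named operator list, validating
## orthonormality (det +1 within 1e-6).
read_oper_list <- function(cats) {
  ol <- cats[["pdbx_struct_oper_list"]]
  if (is.null(ol)) return(list())
  ops <- list()
  for (i in seq_len(nrow(ol))) {
    R <- matrix(NA_real_, 3, 3)
    for (r in 1:3) for (c in 1:3)
      R[r, c] <- as.numeric(ol[[sprintf("matrix[%d][%d]", r, c)]][i])
    t <- vapply(1:3, function(r) as.numeric(ol[[sprintf("vector[%d]", r)]][i]), 0)
    id <- ol$id[i]
    err <- max(abs(t(R) %*% R - diag(3)))
    if (err > 1e-6 || abs(det(R) - 1) > 1e-6)
      stop("operator '", id, "' is not a proper rotation (orthonormality ",
           "residual ", format(err), ")")
    ops[[id]] <- list(rotation = R, translation = t)
  }
  ops
}

## atom_site -> per-entity sphere sets. Radius comes from B_iso when
## present and positive (our fixture convention), else the element table.
atoms_to_entities <- function(as_df, entity_of_row, names_of = NULL,
                              descriptions = NULL, group_prefix = "model") {
  num <- function(col) as.numeric(as_df[[col]])
  x <- num("Cartn_x"); y <- num("Cartn_y"); z <- num("Cartn_z")
  rad <- NULL
  if (!is.null(as_df[["B_iso_or_equiv"]])) {
    rad <- suppressWarnings(as.numeric(as_df[["B_iso_or_equiv"]]))
  }
  elem <- if (!is.null(as_df[["type_symbol"]])) as_df[["type_symbol"]]
          else rep("C", nrow(as_df))
  fallback <- element_radius(elem)
  if (is.null(rad)) rad <- fallback
  bad <- is.na(rad) | rad <= 0
  rad[bad] <- fallback[bad]
  ents <- list()
  for (eid in unique(entity_of_row)) {
    sel <- entity_of_row == eid
    lbl <- if (!is.null(names_of) && !is.null(names_of[[eid]])) names_of[[eid]]
           else eid
    desc <- if (!is.null(descriptions)) descriptions[[eid]] else NULL
    ents[[eid]] <- meso_entity(
      id = eid, label = lbl,
      centers = cbind(x[sel], y[sel], z[sel]), radii = rad[sel],
      group = c(group_prefix, eid), description = desc)
  }
  ents
}

## pdbx_entity_description.{entity_id,text} -> named list of markdown.
read_descriptions <- function(cats) {
  dd <- cats[["pdbx_entity_description"]]
  if (is.null(dd) || is.null(dd$entity_id)) return(NULL)
  stats::setNames(as.list(dd$text), dd$entity_id)
}

operators_to_instances <- function(entity_id, ops) {
  if (length(ops) == 0) return(NULL)
  do.call(rbind, lapply(ops, function(op) {
    q <- matrix_to_quat(op$rotation)
    data.frame(entity_id = entity_id, qx = q[1], qy = q[2], qz = q[3],
               qw = q[4], tx = op$translation[1], ty = op$translation[2],
               tz = op$translation[3], stringsAsFactors = FALSE)
  }))
}

#' Load a standard mmCIF model with biological assembly expansion
#'
#' One entity per distinct `atom_site.label_entity_id`; for each
#' assembly-gen row the operator expression is expanded and applied to
#' every entity owning atoms in the row's chain list. Without assembly
#' categories each entity gets a single identity instance.
#'
#' @param path mmCIF file
#' @return a [meso_scene()]; load warnings are attached as attribute
#'   `"load_report"` (data frame)
#' @export
load_mmcif <- function(path) {
  cats <- cif_parse(path)
  as_df <- cats[["atom_site"]]
  if (is.null(as_df))
    stop("'", path, "' has no atom_site category: not a model file")
  eid <- if (!is.null(as_df$label_entity_id)) as_df$label_entity_id
         else if (!is.null(as_df$label_asym_id)) as_df$label_asym_id
         else rep("1", nrow(as_df))
  ents <- atoms_to_entities(as_df, eid, descriptions = read_descriptions(cats),
                            group_prefix = "model")
  ops <- read_oper_list(cats)
  gen <- cats[["pdbx_struct_assembly_gen"]]
  report <- data.frame(severity = character(), message = character(),
                       stringsAsFactors = FALSE)
  if (is.null(gen) || length(ops) == 0) {
    sc <- meso_scene(ents, NULL, name = basename(path))
  } else {
    asym_of_entity <- lapply(unique(eid), function(e)
      unique(as_df$label_asym_id[eid == e]))
    names(asym_of_entity) <- unique(eid)
    inst <- list()
    for (i in seq_len(nrow(gen))) {
      asyms <- strsplit(gen$asym_id_list[i], ",", fixed = TRUE)[[1]]
      composed <- parse_oper_expression(gen$oper_expression[i], ops)
      for (e in names(ents)) {
        if (length(intersect(asym_of_entity[[e]], asyms)) == 0) next
        inst[[length(inst) + 1]] <- operators_to_instances(e, composed)
      }
    }
    if (length(inst) == 0)
      stop("assembly-gen rows reference no known chains in '", path, "'")
    sc <- meso_scene(ents, do.call(rbind, inst), name = basename(path))
  }
  attr(sc, "load_report") <- report
  sc
}

#' Load a YASARA PetWorld-dialect mmCIF model
#'
#' One entity per `atom_site.pdbx_PDB_model_num`, named from
#' `pdbx_model.name`; instances come from assembly-gen rows whose
#' `PDB_model_num` matches. A declared `pdbx_model.instances` count that
#' disagrees with the generated count is recorded as a warning in the
#' load report; the generated count wins.
#'
#' @param path PetWorld mmCIF file
#' @return a [meso_scene()] with attribute `"load_report"`
#' @export
load_petworld <- function(path) {
  cats <- cif_parse(path)
  as_df <- cats[["atom_site"]]
  if (is.null(as_df)) stop("'", path, "' has no atom_site category")
  if (is.null(as_df$pdbx_PDB_model_num))
    stop("'", path, "' has no atom_site.pdbx_PDB_model_num: not PetWorld dialect")
  model <- as_df$pdbx_PDB_model_num
  pm <- cats[["pdbx_model"]]
  names_of <- NULL; declared <- NULL
  if (!is.null(pm)) {
    key <- if (!is.null(pm$model_num)) pm$model_num
           else as.character(seq_len(nrow(pm)))
    names_of <- stats::setNames(as.list(pm$name), key)
    if (!is.null(pm$instances))
      declared <- stats::setNames(as.integer(pm$instances), key)
  }
  ents <- atoms_to_entities(as_df, model, names_of = names_of,
                            descriptions = read_descriptions(cats),
                            group_prefix = "petworld")
  ops <- read_oper_list(cats)
  gen <- cats[["pdbx_struct_assembly_gen"]]
  report <- data.frame(severity = character(), message = character(),
                       stringsAsFactors = FALSE)
  if (is.null(gen) || is.null(gen$PDB_model_num)) {
    sc <- meso_scene(ents, NULL, name = basename(path))
  } else {
    inst <- list()
    for (i in seq_len(nrow(gen))) {
      mn <- gen$PDB_model_num[i]
      if (is.null(ents[[mn]]))
        stop("assembly-gen row ", i, " references absent model number '",
             mn, "'")
      composed <- parse_oper_expression(gen$oper_expression[i], ops)
      inst[[length(inst) + 1]] <- operators_to_instances(mn, composed)
    }
    instances <- do.call(rbind, inst)
    gen_counts <- table(instances$entity_id)
    for (mn in names(declared)) {
      gc <- if (mn %in% names(gen_counts)) as.integer(gen_counts[[mn]]) else 0L
      if (!is.na(declared[[mn]]) && declared[[mn]] != gc)
        report <- rbind(report, data.frame(
          severity = "warning",
          message = sprintf(paste0("pdbx_model.instances declares %d for ",
                                   "model %s but %d were generated; using %d"),
                            declared[[mn]], mn, gc, gc),
          stringsAsFactors = FALSE))
    }
    sc <- meso_scene(ents, instances, name = basename(path))
  }
  attr(sc, "load_report") <- report
  sc
}

#' Write a load report as JSON lines
#'
#' @param scene a scene with a `"load_report"` attribute
#' @param path output file (one JSON object per finding)
#' @return `path`, invisibly
#' @export
write_load_report <- function(scene, path) {
  rep <- attr(scene, "load_report")
  con <- file(path, "wb"); on.exit(close(con))
  if (!is.null(rep) && nrow(rep) > 0)
    for (i in seq_len(nrow(rep)))
      writeLines(jsonlite::toJSON(as.list(rep[i, ]), auto_unbox = TRUE), con)
  invisible(path)
}
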