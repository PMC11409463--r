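## Deterministic synthetic scenes emulating the geometric archetypes of
## mesoscale models — virus capsid shells (instances on a sphere, oriented
## outward), lipid membrane sheets (a tiled plane), densely packed
## cytoplasm interiors (non-overlapping dart throwing), regular lattices
## and single molecules. Entities are random sphere blobs: real structure
## content is irrelevant to the geometric and visual properties under
## test. Every generator is reproducible from the seed in its spec.

#' Describe a synthetic fixture scene
#'
#' @param kind `"single"`, `"lattice"`, `"capsid-shell"`,
#'   `"membrane-sheet"` or `"packed-interior"`
#' @param n_entities number of distinct entities
#' @param copies instance copies per entity
#' @param spheres_per_entity spheres in each entity blob
#' @param radius_range min/max sphere radius (Angstrom)
#' @param extent overall scene extent (Angstrom): shell diameter, sheet
#'   width, packing box edge
#' @param seed RNG seed, carried in the returned object so every
#'   generated scene is reproducible
#' @return a list of class `fixture_spec`
#' @export
fixture_spec <- function(kind = "packed-interior", n_entities = 3,
                         copies = 10, spheres_per_entity = 30,
                         radius_range = c(1.5, 2.5), extent = 200,
                         seed = 7L) {
  kinds <- c("single", "lattice", "capsid-shell", "membrane-sheet",
             "packed-interior")
  if (!kind %in% kinds)
    stop("unknown fixture kind '", kind, "'; valid: ",
         paste(kinds, collapse = ", "))
  stopifnot(n_entities >= 1, copies >= 1, spheres_per_entity >= 1,
            extent > 0, length(radius_range) == 2,
            all(radius_range > 0))
  structure(list(kind = kind, n_entities = as.integer(n_entities),
                 copies = as.integer(copies),
                 spheres_per_entity = as.integer(spheres_per_entity),
                 radius_range = as.numeric(radius_range),
                 extent = as.numeric(extent), seed = as.integer(seed)),
            class = "fixture_spec")
}

## random blob entity: spheres jittered around the origin
make_blob_entity <- function(id, n_spheres, radius_range, blob_sd, group) {
  centers <- matrix(stats::rnorm(n_spheres * 3, sd = blob_sd), ncol = 3)
  radii <- stats::runif(n_spheres, radius_range[1], radius_range[2])
  meso_entity(id, centers, radii, group = group)
}

## quaternion rotating +z onto unit vector v
quat_z_to <- function(v) {
  z <- c(0, 0, 1)
  d <- sum(z * v)
  if (d > 1 - 1e-12) return(c(0, 0, 0, 1))
  if (d < -1 + 1e-12) return(c(1, 0, 0, 0))       # 180 deg about x
  ax <- c(z[2] * v[3] - z[3] * v[2], z[3] * v[1] - z[1] * v[3],
          z[1] * v[2] - z[2] * v[1])
  s <- sqrt((1 + d) * 2)
  quat_normalize(c(ax / s, s / 2))
}

## Fibonacci-spiral points on the unit sphere: even coverage at any n
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a synthetic scene
#'
#' Deterministic given `spec$seed`. Capsid shells place all instances at
#' the shell radius oriented outward; membrane sheets tile a plane;
#' packed interiors dart-throw instances until bounding spheres stop
#' overlapping (capped attempts).
#'
#' @param spec a [fixture_spec()]
#' @return a [meso_scene()]
#' @export
make_scene <- function(spec) {
  with_seed(spec$seed, {
    blob_sd <- spec$extent / 40 + 2
    ents <- lapply(seq_len(spec$n_entities), function(i) {
      grp <- c(spec$kind, sprintf("class-%d", 1 + (i - 1) %% 3))
      make_blob_entity(sprintf("E%d", i), spec$spheres_per_entity,
                       spec$radius_range, blob_sd, grp)
    })
    entity_bound_r <- vapply(ents, function(e) {
      c0 <- colMeans(e$centers)
      max(sqrt(rowSums((e$centers - matrix(c0, nrow(e$centers), 3,
                                           byrow = TRUE))^2)) + e$radii)
    }, 0)
    n_inst <- spec$n_entities * spec$copies
    eid <- rep(vapply(ents, `[[`, "", "id"), each = spec$copies)

    if (spec$kind == "single") {
      inst <- NULL
    } else if (spec$kind == "capsid-shell") {
      R <- spec$extent / 2
      dirs <- fibonacci_sphere(n_inst)
      qs <- t(apply(dirs, 1, quat_z_to))
      inst <- data.frame(entity_id = eid, qx = qs[, 1], qy = qs[, 2],
                         qz = qs[, 3], qw = qs[, 4],
                         tx = R * dirs[, 1], ty = R * dirs[, 2],
                         tz = R * dirs[, 3], stringsAsFactors = FALSE)
    } else if (spec$kind == "membrane-sheet") {
      side <- ceiling(sqrt(n_inst))
      step <- spec$extent / side
      gx <- ((seq_len(n_inst) - 1) %% side - (side - 1) / 2) * step
      gy <- (floor((seq_len(n_inst) - 1) / side) - (side - 1) / 2) * step
      inst <- data.frame(entity_id = eid, qx = 0, qy = 0, qz = 0, qw = 1,
                         tx = gx, ty = gy, tz = 0, stringsAsFactors = FALSE)
    } else if (spec$kind == "lattice") {
      side <- ceiling(n_inst^(1 / 3))
      step <- spec$extent / side
      k <- seq_len(n_inst) - 1
      inst <- data.frame(entity_id = eid, qx = 0, qy = 0, qz = 0, qw = 1,
                         tx = (k %% side - (side - 1) / 2) * step,
                         ty = (floor(k / side) %% side - (side - 1) / 2) * step,
                         tz = (floor(k / side^2) - (side - 1) / 2) * step,
                         stringsAsFactors = FALSE)
    } else {                                     # packed-interior
      bound_of <- rep(entity_bound_r, each = spec$copies)
      pos <- matrix(NA_real_, n_inst, 3)
      placed_r <- numeric(0)
      max_attempts <- 200L * n_inst
      attempts <- 0L
      for (i in seq_len(n_inst)) {
        ok <- FALSE
        while (!ok) {
          attempts <- attempts + 1L
          if (attempts > max_attempts)
            stop("packed-interior: could not place ", n_inst,
                 " instances in extent ", spec$extent,
                 "; lower the density (fewer copies or larger extent)")
          p <- stats::runif(3, -spec$extent / 2, spec$extent / 2)
          if (i == 1) { ok <- TRUE } else {
            prev <- pos[seq_len(i - 1), , drop = FALSE]
            d <- sqrt(rowSums((prev - matrix(p, i - 1, 3, byrow = TRUE))^2))
            ok <- all(d >= placed_r + bound_of[i])
          }
        }
        pos[i, ] <- p
        placed_r <- c(placed_r, bound_of[i])
      }
      qs <- uniform_rotation(n_inst)
      inst <- data.frame(entity_id = eid, qx = qs[, 1], qy = qs[, 2],
                         qz = qs[, 3], qw = qs[, 4], tx = pos[, 1],
                         ty = pos[, 2], tz = pos[, 3],
                         stringsAsFactors = FALSE)
    }
    ## sheet/lattice keep identity rotations: random orientations would
    ## break the regularity those archetypes are meant to exercise
    sc <- meso_scene(ents, inst,
                     name = sprintf("%s-seed%d", spec$kind, spec$seed),
                     group_keys = c("compartment", "class"))
    assign_colors(sc, "by-group", seed = spec$seed)
  })
}

#' Write a scene as a fixture mmCIF file
#'
#' The standard dialect stores all entities' spheres as atoms (radius in
#' `B_iso_or_equiv`), one chain per entity, with
#' `_pdbx_struct_oper_list` / `_pdbx_struct_assembly_gen` rows
#' reproducing the instances. The petworld dialect stores one model
#' number per entity with `pdbx_model.*` name/instance rows and
#' `PDB_model_num` on the gen rows.
#'
#' @param scene a [meso_scene()]
#' @param path output file
#' @param dialect `"standard"` or `"petworld"`
#' @return `path`, invisibly
#' @export
write_fixture_mmcif <- function(scene, path, dialect = c("standard",
                                                         "petworld")) {
  dialect <- match.arg(dialect)
  ents <- scene$entities
  fmt <- function(x) sprintf("%.3f", x)
  ## atom_site shared by both dialects
  rows <- lapply(seq_along(ents), function(i) {
    e <- ents[[i]]
    n <- nrow(e$centers)
    data.frame(
      group_PDB = rep("HETATM", n), id = seq_len(n),
      type_symbol = rep("C", n), label_atom_id = rep("C1", n),
      label_comp_id = rep("SPH", n),
      label_asym_id = rep(LETTERS[(i - 1) %% 26 + 1], n),
      label_entity_id = rep(e$id, n), label_seq_id = seq_len(n),
      Cartn_x = fmt(e$centers[, 1]), Cartn_y = fmt(e$centers[, 2]),
      Cartn_z = fmt(e$centers[, 3]), occupancy = rep("1.00", n),
      B_iso_or_equiv = fmt(e$radii),
      pdbx_PDB_model_num = rep(if (dialect == "petworld") i else 1L, n),
      stringsAsFactors = FALSE)
  })
  atom_site <- do.call(rbind, rows)
  atom_site$id <- seq_len(nrow(atom_site))

  ## one operator per instance
  ins <- scene$instances
  opers <- lapply(seq_len(nrow(ins)), function(j) {
    q <- c(ins$qx[j], ins$qy[j], ins$qz[j], ins$qw[j])
    R <- quat_to_matrix(q)
    row <- list(id = as.character(j), type = "point symmetry operation")
    for (r in 1:3) for (c in 1:3)
      row[[sprintf("matrix[%d][%d]", r, c)]] <- sprintf("%.9f", R[r, c])
    for (r in 1:3)
      row[[sprintf("vector[%d]", r)]] <- sprintf("%.4f", ins[[c("tx", "ty", "tz")[r]]][j])
    as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
  })
  oper_list <- do.call(rbind, opers)

  gen <- do.call(rbind, lapply(seq_along(ents), function(i) {
    e <- ents[[i]]
    idx <- which(ins$entity_id == e$id)
    if (length(idx) == 0) return(NULL)
    expr <- if (length(idx) == 1) as.character(idx)
            else sprintf("(%d-%d)", min(idx), max(idx))
    ## instances of one entity occupy a contiguous index block in fixture
    ## scenes; guard anyway
    if (!all(idx == seq(min(idx), max(idx)))) expr <- paste(idx, collapse = ",")
    df <- data.frame(assembly_id = "1", oper_expression = expr,
                     asym_id_list = LETTERS[(i - 1) %% 26 + 1],
                     stringsAsFactors = FALSE)
    if (dialect == "petworld") df$PDB_model_num <- as.character(i)
    df
  }))

  cats <- list(atom_site = atom_site,
               pdbx_struct_assembly = data.frame(
                 id = "1", details = "fixture assembly",
                 stringsAsFactors = FALSE),
               pdbx_struct_oper_list = oper_list,
               pdbx_struct_assembly_gen = gen)
  if (dialect == "petworld") {
    counts <- table(ins$entity_id)
    cats$pdbx_model <- data.frame(
      model_num = as.character(seq_along(ents)),
      name = vapply(ents, `[[`, "", "label"),
      instances = as.integer(counts[vapply(ents, `[[`, "", "id")]),
      stringsAsFactors = FALSE)
  }
  descs <- Filter(Negate(is.null), lapply(ents, `[[`, "description"))
  if (length(descs) > 0) {
    cats$pdbx_entity_description <- data.frame(
      entity_id = names(descs), text = unlist(descs),
      stringsAsFactors = FALSE)
  }
  cif_write(cats, path, block = gsub("[^A-Za-z0-9_]", "_", scene$name))
}
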