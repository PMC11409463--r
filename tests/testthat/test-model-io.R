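identity_op <- list(rotation = diag(3), translation = c(0, 0, 0))

test_that("oper expressions expand to the enumerated operator product", {
  expect_equal(length(parse_oper_expression("1", list(`1` = identity_op))), 1)
  ops <- mesoscene:::with_seed(5, {
    o <- lapply(1:5, function(i) random_operator())
    names(o) <- as.character(1:5)
    o
  })
  ## listed order preserved
  r <- parse_oper_expression("1,2,3", ops)
  expect_equal(vapply(r, `[[`, "", "id"), c("1", "2", "3"))
  expect_equal(r[[2]]$rotation, ops[["2"]]$rotation)
  ## Cartesian product with left term applied last: result = O_l . O_r
  r <- parse_oper_expression("(1-3)(4,5)", ops)
  expect_equal(length(r), 6)
  combos <- expand.grid(right = c("4", "5"), left = c("1", "2", "3"))
  for (k in seq_len(nrow(combos))) {
    l <- ops[[as.character(combos$left[k])]]
    rr <- ops[[as.character(combos$right[k])]]
    want_R <- l$rotation %*% rr$rotation
    want_t <- as.numeric(l$rotation %*% rr$translation) + l$translation
    got <- r[[which(vapply(r, `[[`, "", "id") ==
                    paste(combos$left[k], combos$right[k], sep = "*"))]]
    expect_equal(got$rotation, want_R, tolerance = 1e-12)
    expect_equal(got$translation, want_t, tolerance = 1e-12)
  }
  expect_error(parse_oper_expression("1,9", ops), "9")
  expect_error(parse_oper_expression("", ops), "empty")
})

write_min_mmcif <- function(path, centers, opers = NULL, gen = NULL,
                            extra = list()) {
  n <- nrow(centers)
  cats <- c(list(atom_site = data.frame(
    group_PDB = rep("HETATM", n), id = seq_len(n), type_symbol = "C",
    label_atom_id = "C1", label_comp_id = "SPH", label_asym_id = "A",
    label_entity_id = "1", Cartn_x = sprintf("%.3f", centers[, 1]),
    Cartn_y = sprintf("%.3f", centers[, 2]),
    Cartn_z = sprintf("%.3f", centers[, 3]),
    B_iso_or_equiv = "1.700", stringsAsFactors = FALSE)), extra)
  if (!is.null(opers)) cats$pdbx_struct_oper_list <- opers
  if (!is.null(gen)) cats$pdbx_struct_assembly_gen <- gen
  cif_write(cats, path)
}

oper_row <- function(id, R, t) {
  row <- list(id = id, type = "point symmetry operation")
  for (r in 1:3) for (c in 1:3)
    row[[sprintf("matrix[%d][%d]", r, c)]] <- sprintf("%.9f", R[r, c])
  for (r in 1:3) row[[sprintf("vector[%d]", r)]] <- sprintf("%.4f", t[r])
  as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("mmCIF without assembly categories yields identity instances", {
  f <- tempfile(fileext = ".cif")
  write_min_mmcif(f, matrix(c(1, 2, 3), 1, 3))
  sc <- load_mmcif(f)
  expect_equal(length(sc$entities), 1)
  expect_equal(n_instances(sc), 1)
  expect_equal(as.numeric(sc$instances[1, c("qx", "qy", "qz", "qw")]),
               c(0, 0, 0, 1))
  expect_equal(world_spheres(sc, 1)$centers[1, ], c(1, 2, 3),
               tolerance = 1e-9)
})

test_that("assembly expansion applies each printed operator directly", {
  ## 60 operators in one gen row, fixture coordinates transformed by hand
  set.seed(21)
  ops <- lapply(1:60, function(i) random_operator())
  names(ops) <- as.character(1:60)
  centers <- matrix(rnorm(9, sd = 5), 3, 3)
  f <- tempfile(fileext = ".cif")
  write_min_mmcif(f, centers,
                  opers = do.call(rbind, lapply(1:60, function(i)
                    oper_row(as.character(i), ops[[i]]$rotation,
                             ops[[i]]$translation))),
                  gen = data.frame(assembly_id = "1",
                                   oper_expression = "(1-60)",
                                   asym_id_list = "A",
                                   stringsAsFactors = FALSE))
  sc <- load_mmcif(f)
  expect_equal(n_instances(sc), 60)
  cif_centers <- round(centers, 3)   # file stores 3 decimals
  for (i in c(1, 17, 60)) {
    got <- world_spheres(sc, i)$centers
    want <- cif_centers %*% t(ops[[i]]$rotation) +
      matrix(ops[[i]]$translation, 3, 3, byrow = TRUE)
    expect_equal(got, unname(want), tolerance = 2e-4)
  }
})

test_that("disjoint gen rows sum their operator counts", {
  n <- 2
  atoms <- data.frame(
    group_PDB = "HETATM", id = 1:2, type_symbol = "C", label_atom_id = "C1",
    label_comp_id = "SPH", label_asym_id = c("A", "B"),
    label_entity_id = c("1", "2"), Cartn_x = c("0.000", "5.000"),
    Cartn_y = "0.000", Cartn_z = "0.000", B_iso_or_equiv = "1.700",
    stringsAsFactors = FALSE)
  opers <- do.call(rbind, lapply(1:5, function(i)
    oper_row(as.character(i), diag(3), c(i, 0, 0))))
  gen <- data.frame(assembly_id = "1",
                    oper_expression = c("(1-3)", "4,5"),
                    asym_id_list = c("A", "B"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".cif")
  cif_write(list(atom_site = atoms, pdbx_struct_oper_list = opers,
                 pdbx_struct_assembly_gen = gen), f)
  sc <- load_mmcif(f)
  expect_equal(n_instances(sc), 3 + 2)
  expect_equal(sum(sc$instances$entity_id == "1"), 3)
  expect_equal(sum(sc$instances$entity_id == "2"), 2)
})

test_that("format and validation errors are loud and name the culprit", {
  f <- tempfile(fileext = ".cif")
  cif_write(list(pdbx_model = data.frame(name = "x")), f)
  expect_error(load_mmcif(f), "atom_site")
  ## non-orthonormal operator
  bad <- diag(3); bad[1, 1] <- 1.1
  write_min_mmcif(f, matrix(0, 1, 3),
                  opers = oper_row("7", bad, c(0, 0, 0)),
                  gen = data.frame(assembly_id = "1", oper_expression = "7",
                                   asym_id_list = "A",
                                   stringsAsFactors = FALSE))
  expect_error(load_mmcif(f), "'7'")
})

test_that("petworld models load per model number with declared-count warnings", {
  sc0 <- make_scene(fixture_spec("lattice", n_entities = 3, copies = 2,
                                 spheres_per_entity = 4, extent = 60,
                                 seed = 13))
  f <- tempfile(fileext = ".cif")
  write_fixture_mmcif(sc0, f, "petworld")
  sc <- load_petworld(f)
  expect_equal(length(sc$entities), 3)
  expect_equal(unname(table(sc$instances$entity_id)[c("1", "2", "3")]),
               rep(2L, 3), ignore_attr = TRUE)
  expect_equal(nrow(attr(sc, "load_report")), 0)

  ## corrupt the declared instance count -> exactly one warning, generated
  ## count wins
  txt <- readLines(f)
  i <- grep("^'?1'? E1 2$", txt)[1]
  txt[i] <- sub(" 2$", " 5", txt[i])
  writeLines(txt, f)
  sc2 <- load_petworld(f)
  rep2 <- attr(sc2, "load_report")
  expect_equal(nrow(rep2), 1)
  expect_match(rep2$message, "declares 5")
  expect_equal(sum(sc2$instances$entity_id == "1"), 2)

  ## gen row referencing an absent model number
  txt2 <- readLines(f)
  txt2 <- sub("^1 \\((.*)\\) A 1$", "1 (\\1) A 9", txt2)
  writeLines(txt2, f)
  expect_error(load_petworld(f), "absent model number")
})

test_that("petworld single identity model keeps coordinates unchanged", {
  e <- meso_entity("1", matrix(c(3, -2, 7), 1, 3), 1.5, label = "solo")
  sc0 <- meso_scene(list(e))
  f <- tempfile(fileext = ".cif")
  write_fixture_mmcif(sc0, f, "petworld")
  sc <- load_petworld(f)
  expect_equal(world_spheres(sc, 1)$centers[1, ], c(3, -2, 7),
               tolerance = 1e-3)
  expect_equal(sc$entities[["1"]]$label, "solo")
})

test_that("markdown entity descriptions survive the mmCIF round trip", {
  e <- meso_entity("1", matrix(0, 1, 3), 1,
                   description = "A **bold** molecule, see [next](#s2).")
  f <- tempfile(fileext = ".cif")
  write_fixture_mmcif(meso_scene(list(e)), f, "standard")
  sc <- load_mmcif(f)
  expect_equal(sc$entities[["1"]]$description,
               "A **bold** molecule, see [next](#s2).")
})

test_that("load reports serialize as JSON lines", {
  sc <- small_packed(seed = 3, copies = 2)
  attr(sc, "load_report") <- data.frame(
    severity = "warning", message = "declared 5, generated 2",
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".jsonl")
  write_load_report(sc, f)
  lines <- readLines(f)
  expect_equal(length(lines), 1)
  expect_equal(jsonlite::fromJSON(lines[1])$severity, "warning")
})
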