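## Snapshot-based guided tours. A snapshot captures everything that
## determines a frame — camera, per-group styles, clip objects, quality
## preset, labels, markdown description — under a unique key, so applying
## it reproduces the capture-time render bit for bit. Tours replay
## snapshots like a slideshow with spherically interpolated camera
## motion; markdown links in descriptions and labels navigate between
## snapshots and highlight entities or groups.

#' Capture a snapshot of the current viewer state
#'
#' @param scene a [meso_scene()] (its styles are captured)
#' @param camera a [meso_camera()]
#' @param key unique snapshot key
#' @param name display name
#' @param description markdown description (may contain action links)
#' @param clips active list of [meso_clip()]
#' @param preset quality preset name
#' @param labels list of [meso_label()]
#' @param duration seconds this snapshot holds during playback
#' @param existing_keys keys already used in the tour (duplicates error)
#' @return a list of class `meso_snapshot`
#' @export
capture_snapshot <- function(scene, camera, key, name = key,
                             description = "", clips = list(),
                             preset = "quality", labels = list(),
                             duration = 5, existing_keys = character()) {
  if (key %in% existing_keys) stop("duplicate snapshot key '", key, "'")
  stopifnot(duration > 0)
  structure(list(key = key, name = name, description = description,
                 camera = camera, styles = scene$styles, clips = clips,
                 preset = preset, labels = labels, duration = duration),
            class = "meso_snapshot")
}

#' Create a 3D label
#'
#' A label anchors screen-space text at a 3D position; an optional
#' `snapshot_key` makes it interactable (clicking navigates to that
#' snapshot — exported by [play_tour()] as an index map).
#'
#' @param text label text
#' @param anchor numeric(3) world anchor (Angstrom)
#' @param color RGB in \[0, 1\]
#' @param tooltip optional markdown hover text
#' @param snapshot_key optional key of the snapshot this label links to
#' @param font_style,border,tether presentation descriptors (free text)
#' @return a list of class `meso_label`
#' @export
meso_label <- function(text, anchor, color = c(0, 0, 0), tooltip = NULL,
                       snapshot_key = NULL, font_style = "plain",
                       border = "none", tether = "line") {
  structure(list(text = text, anchor = as.numeric(anchor),
                 color = as.numeric(color), tooltip = tooltip,
                 snapshot_key = snapshot_key, font_style = font_style,
                 border = border, tether = tether),
            class = "meso_label")
}

#' Apply a snapshot to a scene
#'
#' @param scene a [meso_scene()]
#' @param snapshot a [capture_snapshot()]
#' @return list: `scene` (styles restored), `camera`, `clips`, `preset`
#' @export
apply_snapshot <- function(scene, snapshot) {
  scene$styles <- snapshot$styles
  list(scene = scene, camera = snapshot$camera, clips = snapshot$clips,
       preset = snapshot$preset)
}

#' Render one snapshot
#'
#' @param scene a [meso_scene()]
#' @param snapshot a [capture_snapshot()]
#' @param settings base [meso_settings()]; the snapshot's preset wins
#' @return H x W x 3 image array
#' @export
render_snapshot <- function(scene, snapshot, settings = meso_settings()) {
  st <- apply_snapshot(scene, snapshot)
  settings$preset <- quality_preset(st$preset)
  render_scene(st$scene, st$camera, settings, st$clips)
}

ease_value <- function(t, easing) {
  switch(easing,
         linear = t,
         smoothstep = t * t * (3 - 2 * t),
         stop("unknown easing '", easing, "'"))
}

camera_quat <- function(camera) {
  b <- camera_basis(camera)
  ## world-to-view rows: right, up, forward (det +1)
  matrix_to_quat(rbind(b$right, b$up, b$forward))
}

#' Interpolate between two cameras
#'
#' Position and target are linearly interpolated after easing;
#' orientation via spherical interpolation of the view quaternion (short
#' arc, so antipodal representations are safe); the up vector comes from
#' the slerped orientation and stays unit length. Endpoints are exact.
#'
#' @param a,b [meso_camera()] endpoints
#' @param t parameter in \[0, 1\]
#' @param easing `"smoothstep"` (default) or `"linear"`
#' @return a [meso_camera()]
#' @export
interpolate_camera <- function(a, b, t, easing = "smoothstep") {
  stopifnot(t >= 0, t <= 1)
  if (t == 0) return(a)
  if (t == 1) return(b)
  s <- ease_value(t, easing)
  pos <- (1 - s) * a$position + s * b$position
  tgt <- (1 - s) * a$target + s * b$target
  q <- quat_slerp(camera_quat(a), camera_quat(b), s)
  R <- quat_to_matrix(q)
  up <- R[2, ]                             # up row of the view matrix
  fwd <- tgt - pos; fwd <- fwd / sqrt(sum(fwd^2))
  if (abs(sum(up * fwd)) > 1 - 1e-9) up <- R[3, ]  # degenerate fallback
  up <- up - sum(up * fwd) * fwd
  up <- up / sqrt(sum(up^2))
  meso_camera(position = pos, target = tgt, up = up,
              fov_y = (1 - s) * a$fov_y + s * b$fov_y,
              near = (1 - s) * a$near + s * b$near,
              far = (1 - s) * a$far + s * b$far)
}

#' Parse markdown action links
#'
#' Recognizes the three navigation schemes in `[text](target)` links:
#' `#key` jumps to the snapshot with that key, `highlight:<name>`
#' highlights an entity, `group:<path>` highlights a group. Other links
#' and malformed markdown are left untouched and produce no action.
#'
#' @param text markdown
#' @return data frame: `link_text`, `kind`
#'   (goto-snapshot/highlight-entity/highlight-group), `target`
#' @export
parse_markdown_actions <- function(text) {
  out <- data.frame(link_text = character(), kind = character(),
                    target = character(), stringsAsFactors = FALSE)
  m <- gregexpr("\\[([^]]*)\\]\\(([^)]+)\\)", text, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  links <- regmatches(text, list(m))[[1]]
  for (lk in links) {
    txt <- sub("^\\[([^]]*)\\].*$", "\\1", lk)
    tgt <- sub("^.*\\(([^)]+)\\)$", "\\1", lk)
    if (startsWith(tgt, "#")) {
      out <- rbind(out, data.frame(link_text = txt, kind = "goto-snapshot",
                                   target = substring(tgt, 2),
                                   stringsAsFactors = FALSE))
    } else if (startsWith(tgt, "highlight:")) {
      out <- rbind(out, data.frame(link_text = txt, kind = "highlight-entity",
                                   target = substring(tgt, 11),
                                   stringsAsFactors = FALSE))
    } else if (startsWith(tgt, "group:")) {
      out <- rbind(out, data.frame(link_text = txt, kind = "highlight-group",
                                   target = substring(tgt, 7),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Assemble a tour
#'
#' @param snapshots list of [capture_snapshot()] (unique keys)
#' @param name tour name
#' @return a list of class `meso_tour`
#' @export
meso_tour <- function(snapshots, name = "tour") {
  keys <- vapply(snapshots, `[[`, "", "key")
  if (anyDuplicated(keys)) stop("duplicate snapshot keys: ",
                                paste(keys[duplicated(keys)], collapse = ", "))
  structure(list(name = name, snapshots = snapshots), class = "meso_tour")
}

#' Validate a tour against a scene
#'
#' Reports dangling label `snapshot_key`s, dangling `goto-snapshot`
#' markdown targets, and style group paths absent from the scene.
#'
#' @param tour a [meso_tour()]
#' @param scene the scene the tour plays on (or `NULL` to skip group
#'   checks)
#' @return data frame `severity`, `message`; zero rows = valid
#' @export
validate_tour <- function(tour, scene = NULL) {
  sev <- character(); msg <- character()
  note <- function(s, m) { sev <<- c(sev, s); msg <<- c(msg, m) }
  keys <- vapply(tour$snapshots, `[[`, "", "key")
  for (sn in tour$snapshots) {
    for (lb in sn$labels)
      if (!is.null(lb$snapshot_key) && !(lb$snapshot_key %in% keys))
        note("error", sprintf("label '%s' in snapshot '%s' links to unknown key '%s'",
                              lb$text, sn$key, lb$snapshot_key))
    acts <- parse_markdown_actions(sn$description)
    for (i in seq_len(nrow(acts)))
      if (acts$kind[i] == "goto-snapshot" && !(acts$target[i] %in% keys))
        note("error", sprintf("snapshot '%s' description links to unknown key '%s'",
                              sn$key, acts$target[i]))
    if (!is.null(scene)) {
      known <- scene_groups(scene)
      for (g in setdiff(names(sn$styles), known))
        note("warning", sprintf("snapshot '%s' styles unknown group '%s'",
                                sn$key, g))
    }
  }
  data.frame(severity = sev, message = msg, stringsAsFactors = FALSE)
}

## ---- tour JSON serialization (canonical: sorted keys, UTF-8, LF) ----

camera_to_json <- function(c) sorted_obj(
  far = c$far, fov_y = c$fov_y, near = c$near,
  position = as.numeric(c$position), target = as.numeric(c$target),
  up = as.numeric(c$up))

json_to_camera <- function(j) meso_camera(
  position = unlist(j$position), target = unlist(j$target),
  up = unlist(j$up), fov_y = j$fov_y, near = j$near, far = j$far)

clip_to_json <- function(cl) sorted_obj(
  applies_to = as.list(cl$applies_to), invert = cl$invert,
  kind = cl$kind,
  params = if (length(cl$params)) cl$params[order(names(cl$params))]
           else list(),
  rotation = as.numeric(cl$rotation),
  translation = as.numeric(cl$translation))

json_to_clip <- function(j) meso_clip(
  kind = j$kind, rotation = unlist(j$rotation),
  translation = unlist(j$translation),
  params = lapply(j$params, function(p) unlist(p)),
  invert = isTRUE(j$invert), applies_to = unlist(j$applies_to) %||% character())

`%||%` <- function(a, b) if (is.null(a)) b else a

label_to_json <- function(lb) sorted_obj(
  anchor = as.numeric(lb$anchor), border = lb$border,
  color = as.numeric(lb$color), font_style = lb$font_style,
  snapshot_key = lb$snapshot_key, tether = lb$tether, text = lb$text,
  tooltip = lb$tooltip)

json_to_label <- function(j) meso_label(
  text = j$text, anchor = unlist(j$anchor), color = unlist(j$color),
  tooltip = j$tooltip, snapshot_key = j$snapshot_key,
  font_style = j$font_style, border = j$border, tether = j$tether)

#' Write a tour as canonical JSON
#'
#' @param tour a [meso_tour()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_tour <- function(tour, path) {
  snaps <- lapply(tour$snapshots, function(sn) {
    styles <- sn$styles[order(names(sn$styles))]
    sorted_obj(
      camera = camera_to_json(sn$camera),
      clips = lapply(sn$clips, clip_to_json),
      description = sn$description, duration = sn$duration,
      key = sn$key, labels = lapply(sn$labels, label_to_json),
      name = sn$name, preset = sn$preset,
      styles = lapply(styles, style_to_json))
  })
  doc <- sorted_obj(name = tour$name, schema_version = 1L,
                    snapshots = unname(snaps))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(charToRaw(as.character(js)), charToRaw("\n")), con)
  invisible(path)
}

#' Read a tour from JSON
#'
#' @param path tour file written by [write_tour()]
#' @return a [meso_tour()]
#' @export
read_tour <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  snaps <- lapply(doc$snapshots, function(j) {
    structure(list(
      key = j$key, name = j$name, description = j$description,
      camera = json_to_camera(j$camera),
      styles = lapply(j$styles, json_to_style),
      clips = lapply(j$clips, json_to_clip),
      preset = j$preset,
      labels = lapply(j$labels, json_to_label),
      duration = j$duration), class = "meso_snapshot")
  })
  meso_tour(snaps, name = doc$name)
}

#' Play a tour as an image sequence
#'
#' Per consecutive snapshot pair, `frames` interpolated renders are
#' emitted (t from 0 to 1); the first and last frames of each transition
#' are bit-identical to the endpoint snapshots' renders. Non-camera
#' state (styles, clips, preset) snaps at the end of the transition. For
#' a single-snapshot tour one frame is emitted.
#'
#' @param tour a [meso_tour()]
#' @param scene a [meso_scene()]
#' @param frames renders per transition (>= 2 for a real transition)
#' @param settings base [meso_settings()]
#' @param easing camera easing name
#' @return list: `frames` (list of image arrays), `index_map` (named
#'   integer: interactable label text -> frame index of its target
#'   snapshot)
#' @export
play_tour <- function(tour, scene, frames = 5,
                      settings = meso_settings(), easing = "smoothstep") {
  ns <- length(tour$snapshots)
  if (ns == 0) stop("empty tour")
  v <- validate_tour(tour, scene)
  if (any(v$severity == "error"))
    stop("tour does not validate:\n  ",
         paste(v$message[v$severity == "error"], collapse = "\n  "))
  imgs <- list()
  if (ns == 1) {
    imgs[[1]] <- render_snapshot(scene, tour$snapshots[[1]], settings)
  } else {
    for (p in seq_len(ns - 1)) {
      a <- tour$snapshots[[p]]; b <- tour$snapshots[[p + 1]]
      for (k in seq_len(frames)) {
        t <- (k - 1) / (frames - 1)
        if (t == 0) {
          img <- render_snapshot(scene, a, settings)
        } else if (t == 1) {
          img <- render_snapshot(scene, b, settings)
        } else {
          cam <- interpolate_camera(a$camera, b$camera, t, easing)
          st <- apply_snapshot(scene, a)     # non-camera state holds until t=1
          s2 <- settings; s2$preset <- quality_preset(a$preset)
          img <- render_scene(st$scene, cam, s2, st$clips)
        }
        imgs[[length(imgs) + 1]] <- img
      }
    }
  }
  ## frame index of each snapshot's exact render
  keys <- vapply(tour$snapshots, `[[`, "", "key")
  snap_frame <- if (ns == 1) 1L else ifelse(seq_len(ns) == 1, 1L,
                                            (seq_len(ns) - 1L) * frames)
  names(snap_frame) <- keys
  index_map <- integer()
  for (sn in tour$snapshots)
    for (lb in sn$labels)
      if (!is.null(lb$snapshot_key))
        index_map[lb$text] <- snap_frame[[lb$snapshot_key]]
  list(frames = imgs, index_map = index_map, snapshot_frames = snap_frame)
}

## minimal markdown -> HTML for the storyboard (headings, paragraphs,
## links; action links become anchors)
markdown_to_html <- function(text) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  html <- esc(text)
  html <- gsub("\\[([^]]*)\\]\\(([^)]+)\\)", "<a href=\"\\2\">\\1</a>", html)
  paras <- strsplit(html, "\n\n+")[[1]]
  paras <- vapply(paras, function(p) {
    if (grepl("^#+ ", p)) {
      lvl <- nchar(sub("^(#+) .*$", "\\1", p))
      sprintf("<h%d>%s</h%d>", lvl, sub("^#+ ", "", p), lvl)
    } else sprintf("<p>%s</p>", p)
  }, "")
  paste(paras, collapse = "\n")
}

#' Export an HTML storyboard of a tour
#'
#' One section per snapshot: its rendered image plus the markdown
#' description rendered to HTML.
#'
#' @param tour a [meso_tour()]
#' @param image_files character: one image path per snapshot (relative
#'   paths are kept as-is in the HTML)
#' @param path output .html file
#' @return `path`, invisibly
#' @export
storyboard_html <- function(tour, image_files, path) {
  stopifnot(length(image_files) == length(tour$snapshots))
  body <- vapply(seq_along(tour$snapshots), function(i) {
    sn <- tour$snapshots[[i]]
    sprintf(paste0("<section id=\"%s\">\n<h2>%s</h2>\n",
                   "<img src=\"%s\" alt=\"%s\"/>\n%s\n</section>"),
            sn$key, sn$name, image_files[i], sn$key,
            markdown_to_html(sn$description))
  }, "")
  html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
            sprintf("<title>%s</title></head><body>", tour$name),
            sprintf("<h1>%s</h1>", tour$name), body, "</body></html>")
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(html, con, sep = "\n")
  invisible(path)
}
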