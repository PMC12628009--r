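## Per-frame raster annotations: semantic label maps (anatomy rendered with a
## fixed label id per structure), depth maps, amodal / occlusion-resolved
## instrument masks, visibility states and pseudo-chromadepth images.
##
## All rasters come from the deterministic software z-buffer in
## src/raster.cpp; identical scenes give byte-identical rasters.

EDGE_SUBDIV_PX <- 16     # projected-edge length triggering subdivision
OCCLUSION_TOL_MM <- 1    # depth slack when testing occlusion

#' Render a semantic label map and depth map
#'
#' Software z-buffer rasterization of posed meshes: each pixel carries the
#' label id of the nearest surface (0 = background) and its depth along
#' camera +Z in mm (0 = empty).  Triangles with any vertex behind
#' `z_near` = 0.1 mm are clipped; projected edges longer than 16 px are
#' subdivided before lens distortion is applied.
#'
#' @param camera a [camera_model()].
#' @param posed_meshes list of `list(mesh, transform, label_id)` with
#'   `transform` the mesh -> camera-optical-frame pose.
#' @param legend optional named character vector `label_id -> name`; built
#'   from mesh names when omitted.
#' @return `list(labels, depth, legend)`: `labels` an integer
#'   height x width matrix, `depth` numeric height x width (mm).
#' @export
render_label_map <- function(camera, posed_meshes, legend = NULL) {
  stopifnot(is_camera_model(camera))
  H <- camera$height; W <- camera$width
  labels <- matrix(0L, H, W)
  depth <- matrix(0, H, W)
  cp <- camera_param_vector(camera)
  for (pm in posed_meshes) {
    lab <- as.integer(pm$label_id)
    if (lab < 1L || lab > 255L)
      sl_error("label_range", "render_label_map: label_id outside [1, 255]")
    vcam <- rt_apply(pm$transform, pm$mesh$vertices)
    cpp_render_mesh(vcam, pm$mesh$faces - 1L, lab, cp, W, H,
                    Z_NEAR, EDGE_SUBDIV_PX, labels, depth)
  }
  if (is.null(legend)) {
    legend <- stats::setNames(
      vapply(posed_meshes, function(pm) pm$mesh$name, ""),
      vapply(posed_meshes, function(pm) as.character(pm$label_id), ""))
  }
  list(labels = labels, depth = depth, legend = legend)
}

## instrument shaft proxy: capsule of tool_radius around the tip-to-array
## segment (the physical shaft runs from the tip towards the tracked array),
## truncated at shaft_length
instrument_capsule <- function(tip_cam, array_cam, tool_radius, shaft_length) {
  d <- array_cam - tip_cam
  len <- sqrt(sum(d^2))
  if (len < 1e-9) d <- c(0, 0, 1) else d <- d / len
  mesh_capsule(tip_cam + d * min(len, shaft_length), tip_cam, tool_radius)
}

#' Render per-instrument binary masks
#'
#' The shaft mesh is rendered if the instrument provides one, otherwise a
#' capsule of `tool_radius` around the tip-to-array segment.  With
#' `amodal = TRUE` anatomy occlusion is ignored (the full silhouette is
#' returned); with `amodal = FALSE` pixels where the anatomy depth map is
#' nearer than the instrument surface are removed.
#'
#' @param camera a [camera_model()].
#' @param instruments list of `list(name, tip_cam, array_cam, tool_radius,
#'   shaft_length, valid)` -- poses in the camera optical frame, mm.
#' @param depth anatomy depth map from [render_label_map()] (mm; used when
#'   `amodal = FALSE`).
#' @param amodal logical.
#' @return Named list per instrument: `list(mask (logical matrix), valid,
#'   visibility)`; invalid poses give an all-FALSE mask flagged invalid.
#' @export
render_instrument_masks <- function(camera, instruments, depth = NULL,
                                    amodal = TRUE) {
  H <- camera$height; W <- camera$width
  cp <- camera_param_vector(camera)
  out <- list()
  for (ins in instruments) {
    if (!isTRUE(ins$valid)) {
      out[[ins$name]] <- list(mask = matrix(FALSE, H, W), valid = FALSE,
                              visibility = NULL)
      next
    }
    caps <- if (!is.null(ins$shaft_mesh)) ins$shaft_mesh
            else instrument_capsule(ins$tip_cam, ins$array_cam,
                                    ins$tool_radius, ins$shaft_length)
    lb <- matrix(0L, H, W); zb <- matrix(0, H, W)
    cpp_render_mesh(caps$vertices, caps$faces - 1L, 1L, cp, W, H,
                    Z_NEAR, EDGE_SUBDIV_PX, lb, zb)
    mask <- lb > 0L
    if (!amodal && !is.null(depth)) {
      occluded_px <- depth > 0 & zb > 0 & depth < zb - OCCLUSION_TOL_MM
      mask <- mask & !occluded_px
    }
    vis <- visibility(camera, ins$tip_cam, depth)
    out[[ins$name]] <- list(mask = mask, valid = TRUE, visibility = vis)
  }
  out
}

#' Visibility of a 3D point w.r.t. the camera and a depth map
#'
#' `behind_camera` when z <= z_near; `off_screen` when the projected pixel
#' falls outside the image; otherwise `on_screen` with an `occluded` flag set
#' when the point lies more than 1 mm behind the rendered surface at its
#' pixel.  `occluded` is only defined (non-NA) when on screen.
#'
#' @param camera a [camera_model()].
#' @param p numeric(3) point in the camera optical frame, mm.
#' @param depth optional depth map (mm) for the occlusion test.
#' @return `list(state, occluded, u, v)`.
#' @export
visibility <- function(camera, p, depth = NULL) {
  pr <- project_point(camera, p)
  if (pr$behind[1])
    return(list(state = "behind_camera", occluded = NA, u = NA, v = NA))
  u <- pr$u[1]; v <- pr$v[1]
  ui <- round(u); vi <- round(v)
  if (ui < 0 || ui > camera$width - 1 || vi < 0 || vi > camera$height - 1)
    return(list(state = "off_screen", occluded = NA, u = u, v = v))
  occ <- FALSE
  if (!is.null(depth)) {
    dz <- depth[vi + 1L, ui + 1L]
    occ <- dz > 0 && p[3] > dz + OCCLUSION_TOL_MM
  }
  list(state = "on_screen", occluded = occ, u = u, v = v)
}

#' Pseudo-chromadepth rendering of a depth map
#'
#' Linear hue ramp from red (near) to blue (far) over `[z_min, z_max]`,
#' clamped; the ramp runs hue 0 deg (red) -> 240 deg (blue) at full
#' saturation and value, so the midpoint depth maps to green.  Background
#' (depth 0) is black.
#'
#' @param depth height x width depth map, mm.
#' @param z_min,z_max ramp range, mm, `z_min < z_max`.
#' @return height x width x 3 integer array, 0-255.
#' @export
render_chromadepth <- function(depth, z_min, z_max) {
  stopifnot(z_min < z_max)
  u <- pmin(pmax((depth - z_min) / (z_max - z_min), 0), 1)
  hue <- 240 * u / 360
  cols <- grDevices::hsv(hue, 1, 1)
  rgb <- grDevices::col2rgb(cols)
  H <- nrow(depth); W <- ncol(depth)
  out <- array(0L, c(H, W, 3L))
  bg <- depth == 0
  for (k in 1:3) {
    ch <- matrix(as.integer(rgb[k, ]), H, W)
    ch[bg] <- 0L
    out[, , k] <- ch
  }
  out
}

#' Render all annotation rasters for one video frame
#'
#' Resolves the scene at frame time `t`, renders the anatomy label/depth maps
#' in the camera frame, and the instrument masks.  When the camera chain is
#' invalid at `t` the frame is still emitted, flagged `valid = FALSE`, so
#' downstream datasets stay aligned with the video clock.
#'
#' @param session a `surg_session`.
#' @param t frame time, s.
#' @param amodal passed to [render_instrument_masks()].
#' @param max_gap replay gap policy, s.
#' @return `list(t, valid, labels, depth, legend, masks)`.
#' @export
render_frame <- function(session, t, amodal = TRUE,
                         max_gap = DEFAULT_MAX_GAP) {
  cam <- session$camera$model
  camf <- session$camera$camera_frame
  H <- cam$height; W <- cam$width
  ## camera pose in patient frame
  camq <- resolve_transform(session, camf, session$patient_frame, t, max_gap)
  if (!camq$valid)
    return(list(t = t, valid = FALSE, labels = matrix(0L, H, W),
                depth = matrix(0, H, W), legend = character(), masks = list()))
  posed <- lapply(session$anatomies, function(a) {
    mesh_to_cam <- if (a$frame == session$patient_frame) camq$transform
      else rt_compose(camq$transform,
                      resolve_transform(session, session$patient_frame,
                                        a$frame, t, max_gap)$transform)
    list(mesh = a$mesh, transform = mesh_to_cam, label_id = a$label_id)
  })
  lm <- render_label_map(cam, posed)
  inst <- lapply(session$instruments, function(ins) {
    tipq <- resolve_transform(session, camf, ins$tip_frame, t, max_gap)
    arrq <- resolve_transform(session, camf, ins$array_frame, t, max_gap)
    if (!tipq$valid || !arrq$valid)
      return(list(name = ins$name, valid = FALSE))
    list(name = ins$name, tip_cam = tipq$transform$t,
         array_cam = arrq$transform$t, tool_radius = ins$tool_radius,
         shaft_length = ins$shaft_length, valid = TRUE)
  })
  masks <- render_instrument_masks(cam, inst, lm$depth, amodal = amodal)
  list(t = t, valid = TRUE, labels = lm$labels, depth = lm$depth,
       legend = lm$legend, masks = masks)
}

#' Render label maps and masks for a whole session to disk
#'
#' Writes `labels/%06d.png` (8-bit labels) + `labels/legend.json`,
#' `depth/%06d.png` (16-bit, 0.1 mm units) and
#' `masks/<instrument>/%06d.png` under `out_dir`.
#'
#' @param session a `surg_session`.
#' @param out_dir output directory.
#' @param amodal render amodal (TRUE) or occlusion-resolved (FALSE)
#'   instrument masks.
#' @param frames optional integer subset of frame indices (1-based).
#' @param write_depth also write depth PNGs (default TRUE).
#' @return Invisibly, the number of frames rendered.
#' @export
render_session <- function(session, out_dir, amodal = TRUE, frames = NULL,
                           write_depth = TRUE) {
  times <- session$frame_clock$times
  if (is.null(frames)) frames <- seq_along(times)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  if (write_depth)
    dir.create(file.path(out_dir, "depth"), recursive = TRUE, showWarnings = FALSE)
  for (ins in session$instruments)
    dir.create(file.path(out_dir, "masks", ins$name), recursive = TRUE,
               showWarnings = FALSE)
  legend <- NULL
  cam <- session$camera$model
  camf <- session$camera$camera_frame
  pf <- session$patient_frame
  ## resolve all needed chains once, on the frame clock
  sub <- times[frames]
  camch <- resolve_chain_series(session, camf, pf, sub)
  anat_static <- vapply(session$anatomies, function(a) a$frame == pf, TRUE)
  tipch <- lapply(session$instruments, function(ins)
    resolve_chain_series(session, camf, ins$tip_frame, sub))
  arrch <- lapply(session$instruments, function(ins)
    resolve_chain_series(session, camf, ins$array_frame, sub))
  H <- cam$height; W <- cam$width
  for (fi in seq_along(frames)) {
    i <- frames[fi]
    if (camch$valid[fi]) {
      camq <- rigid_transform(camch$Q[fi, ], camch$T[fi, ])
      posed <- lapply(seq_along(session$anatomies), function(ai) {
        a <- session$anatomies[[ai]]
        tr <- if (anat_static[ai]) camq
          else rt_compose(camq, resolve_transform(session, pf, a$frame,
                                                  times[i])$transform)
        list(mesh = a$mesh, transform = tr, label_id = a$label_id)
      })
      lm <- render_label_map(cam, posed)
      inst <- lapply(seq_along(session$instruments), function(k) {
        ins <- session$instruments[[k]]
        if (!tipch[[k]]$valid[fi] || !arrch[[k]]$valid[fi])
          return(list(name = ins$name, valid = FALSE))
        list(name = ins$name, tip_cam = tipch[[k]]$T[fi, ],
             array_cam = arrch[[k]]$T[fi, ], tool_radius = ins$tool_radius,
             shaft_length = ins$shaft_length, valid = TRUE)
      })
      masks <- render_instrument_masks(cam, inst, lm$depth, amodal = amodal)
      fr <- list(valid = TRUE, labels = lm$labels, depth = lm$depth,
                 legend = lm$legend, masks = masks)
    } else {
      fr <- list(valid = FALSE, labels = matrix(0L, H, W),
                 depth = matrix(0, H, W), legend = character(),
                 masks = list())
    }
    write_png_gray(fr$labels, file.path(out_dir, "labels",
                                        sprintf("%06d.png", i)))
    if (write_depth)
      write_depth_png(fr$depth, file.path(out_dir, "depth",
                                          sprintf("%06d.png", i)))
    for (nm in names(fr$masks))
      write_png_gray(fr$masks[[nm]]$mask * 255L,
                     file.path(out_dir, "masks", nm, sprintf("%06d.png", i)))
    if (is.null(legend) && fr$valid) legend <- fr$legend
  }
  if (is.null(legend))
    legend <- stats::setNames(
      vapply(session$anatomies, `[[`, "", "name"),
      vapply(session$anatomies, function(a) as.character(a$label_id), ""))
  writeLines(jsonlite::toJSON(as.list(legend), auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(out_dir, "labels", "legend.json"))
  invisible(length(frames))
}
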