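# shared fixtures: small geometries and a standard normal panel

std_panel <- function() {
  gt_panel(rbc = 4.5, hb = 14, plt = 250, wbc = 7)
}

small_geom2 <- function(area = 0.04) chamber_geometry(2, counting_area = area)
small_geom1 <- function(area = 0.25) chamber_geometry(1, counting_area = area)

# deterministic raster with hand-placed red cells (no noise)
disc_field <- function(side, xs, ys, d = 7.4, class = "rbc",
                       pixel_scale = 0.5) {
  cells <- data.frame(x = xs, y = ys, diameter_um = d, class = class,
                      amp = 1)
  render_field(side, cells, pixel_scale, noise_sd = 0)
}

# brute-force oracle: connected components of the IoU graph, survivor by
# the documented tie-break, written independently of merge_detections
merge_oracle <- function(det, thr) {
  n <- nrow(det)
  if (n <= 1) return(det)
  iou <- function(i, j) {
    ix <- max(0, min(det$x1[i], det$x1[j]) - max(det$x0[i], det$x0[j]))
    iy <- max(0, min(det$y1[i], det$y1[j]) - max(det$y0[i], det$y0[j]))
    inter <- ix * iy
    a1 <- (det$x1[i] - det$x0[i]) * (det$y1[i] - det$y0[i])
    a2 <- (det$x1[j] - det$x0[j]) * (det$y1[j] - det$y0[j])
    inter / (a1 + a2 - inter)
  }
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    adj[i, j] <- adj[j, i] <- iou(i, j) >= thr
  comp <- rep(0L, n)
  cur <- 0L
  for (i in 1:n) if (comp[i] == 0L) {
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) for (j in which(adj[f, ]))
        if (comp[j] == 0L) { comp[j] <- cur; nxt <- c(nxt, j) }
      frontier <- nxt
    }
  }
  keep <- vapply(split(seq_len(n), comp), function(members) {
    d <- det[members, ]
    area <- (d$x1 - d$x0) * (d$y1 - d$y0)
    o <- order(-d$confidence, -area, d$x0, d$y0)
    members[o[1]]
  }, integer(1))
  det[sort(keep), ]
}

random_boxes <- function(n, seed) {
  set.seed(seed)
  x0 <- runif(n, 0, 80); y0 <- runif(n, 0, 80)
  w <- runif(n, 4, 16); h <- runif(n, 4, 16)
  data.frame(x0 = x0, y0 = y0, x1 = x0 + w, y1 = y0 + h,
             cx = x0 + w / 2, cy = y0 + h / 2,
             label = "rbc", confidence = runif(n),
             diameter_um = 7, source_tile = 1L)
}
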