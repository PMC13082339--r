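# Small hand-built tissues used across the unit tests.

# A vertical 1 x n column of w x h rectangular cells sharing walls; the
# bottom cell can be marked as attachment.
column_tissue <- function(n, w = 10, h = 10, attach_bottom = TRUE) {
  pos <- NULL
  for (j in 0:n) pos <- rbind(pos, c(-w / 2, j * h), c(w / 2, j * h))
  rings <- lapply(seq_len(n), function(j) {
    b <- 2 * (j - 1)
    c(b + 1L, b + 2L, b + 4L, b + 3L)
  })
  type <- c(if (attach_bottom) "attachment" else "blade",
            rep("blade", n - 1))
  zone <- c(if (attach_bottom) "attachment" else "proliferative",
            rep("proliferative", n - 1))
  new_tissue(pos, is_base = pos[, 2] == 0, ring = rings,
             merophyte = rep(NA_integer_, n), type = type, zone = zone,
             apical_id = n)
}

# A single-cell tissue from an arbitrary counter-clockwise polygon.
one_cell_tissue <- function(p, polarity = c(0, 1)) {
  tis <- new_tissue(p, is_base = seq_len(nrow(p)) == 1, ring = list(seq_len(nrow(p))),
                    type = "blade", zone = "proliferative")
  tis$polarity[1, ] <- polarity
  tis
}

# Random convex polygon with nv vertices (counter-clockwise), radius ~ r.
random_convex_polygon <- function(nv, r = 1) {
  th <- sort(stats::runif(nv, 0, 2 * pi))
  rad <- r * (0.6 + 0.4 * stats::runif(nv))
  cbind(rad * cos(th), rad * sin(th))
}

# Minimal parameter stub for zone / rate unit tests.
stub_params <- function(...) {
  p <- scenario_params("wt_upper")
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}
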