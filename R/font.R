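# Built-in fixed-width digit typeface ("blockface"): one glyph per digit class,
# drawn on a 16 x 10 binary grid with 2-px strokes. All stimuli use this single
# typeface at a single size so that digit identity and position are the only
# sources of variation in a scene.

.blockface_rows <- list(
  `0` = c(
    "..######..",
    ".########.",
    "###....###",
    "##......##",
    "##......##",
    "##......##",
    "##......##",
    "##......##",
    "##......##",
    "##......##",
    "##......##",
    "##......##",
    "##......##",
    "###....###",
    ".########.",
    "..######.."),
  `1` = c(
    "....##....",
    "...###....",
    "..####....",
    ".#####....",
    "....##....",
    "....##....",
    "....##....",
    "....##....",
    "....##....",
    "....##....",
    "....##....",
    "....##....",
    "....##....",
    "....##....",
    ".########.",
    ".########."),
  `2` = c(
    "..######..",
    ".########.",
    "###....###",
    "##......##",
    "........##",
    ".......###",
    "......###.",
    ".....###..",
    "....###...",
    "...###....",
    "..###.....",
    ".###......",
    "###.......",
    "##........",
    "##########",
    "##########"),
  `3` = c(
    "..######..",
    ".########.",
    "###....###",
    "........##",
    "........##",
    ".......###",
    "...#####..",
    "...######.",
    "........##",
    "........##",
    "........##",
    "........##",
    "##......##",
    "###....###",
    ".########.",
    "..######.."),
  `4` = c(
    ".......##.",
    "......###.",
    ".....####.",
    "....##.##.",
    "...##..##.",
    "..##...##.",
    ".##....##.",
    "##.....##.",
    "##.....##.",
    "##########",
    "##########",
    ".......##.",
    ".......##.",
    ".......##.",
    ".......##.",
    ".......##."),
  `5` = c(
    "##########",
    "##########",
    "##........",
    "##........",
    "##........",
    "##........",
    "########..",
    "#########.",
    ".......###",
    "........##",
    "........##",
    "........##",
    "##......##",
    "###....###",
    ".########.",
    "..######.."),
  `6` = c(
    "..######..",
    ".########.",
    "###....###",
    "##........",
    "##........",
    "##........",
    "########..",
    "#########.",
    "###....###",
    "##......##",
    "##......##",
    "##......##",
    "##......##",
    "###....###",
    ".########.",
    "..######.."),
  `7` = c(
    "##########",
    "##########",
    "........##",
    ".......###",
    ".......##.",
    "......###.",
    "......##..",
    ".....###..",
    ".....##...",
    "....###...",
    "....##....",
    "...###....",
    "...##.....",
    "...##.....",
    "..###.....",
    "..##......"),
  `8` = c(
    "..######..",
    ".########.",
    "###....###",
    "##......##",
    "##......##",
    "###....###",
    ".########.",
    ".########.",
    "###....###",
    "##......##",
    "##......##",
    "##......##",
    "##......##",
    "###....###",
    ".########.",
    "..######.."),
  `9` = c(
    "..######..",
    ".########.",
    "###....###",
    "##......##",
    "##......##",
    "##......##",
    "###....###",
    ".#########",
    "..########",
    "........##",
    "........##",
    "........##",
    "###....###",
    "###....###",
    ".########.",
    "..######..")
)

.font_cache <- new.env(parent = emptyenv())

# 16 x 10 binary matrix for one digit class (0-9).
glyph_bitmap <- function(class) {
  stopifnot(length(class) == 1, class %in% 0:9)
  key <- as.character(class)
  if (is.null(.font_cache[[key]])) {
    rows <- .blockface_rows[[key]]
    m <- do.call(rbind, lapply(rows, function(r) {
      as.integer(strsplit(r, "")[[1]] == "#")
    }))
    storage.mode(m) <- "double"
    .font_cache[[key]] <- m
  }
  .font_cache[[key]]
}

# Nearest-neighbour scaling of a glyph bitmap to `height` pixels (width keeps
# the 10:16 aspect ratio). Cached per (class, height).
glyph_scaled <- function(class, height) {
  key <- paste0("s", class, "_", height)
  if (is.null(.font_cache[[key]])) {
    g <- glyph_bitmap(class)
    w <- max(1L, as.integer(round(height * ncol(g) / nrow(g))))
    ri <- floor((seq_len(height) - 0.5) * nrow(g) / height) + 1
    ci <- floor((seq_len(w) - 0.5) * ncol(g) / w) + 1
    .font_cache[[key]] <- g[ri, ci, drop = FALSE]
  }
  .font_cache[[key]]
}
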