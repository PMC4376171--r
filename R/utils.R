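# Internal geometry and parsing helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "mdescape_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stopf(fmt, ...)
  invisible(TRUE)
}

#' @noRd
as_xyz <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stopf("coordinate matrix must have 3 columns, got %d", ncol(x))
  storage.mode(x) <- "double"
  x
}

## Squared distances from each row of X (n x 3) to point p (length 3).
dist2_to_point <- function(X, p) {
  dx <- X[, 1L] - p[1L]; dy <- X[, 2L] - p[2L]; dz <- X[, 3L] - p[3L]
  dx * dx + dy * dy + dz * dz
}

min_dist_to_set <- function(p, X) {
  if (nrow(X) == 0L) stopf("empty coordinate set in distance computation")
  sqrt(min(dist2_to_point(X, p)))
}

## Minimum distance from each of k centers (k x 3) to a point cloud X (n x 3).
## Returns length-k vector. Uses |a-b|^2 = |a|^2 + |b|^2 - 2 a.b.
cross_min_dist <- function(centers, X) {
  centers <- as_xyz(centers); X <- as_xyz(X)
  if (nrow(X) == 0L) stopf("empty coordinate set in distance computation")
  g <- tcrossprod(centers, X)                       # k x n
  d2 <- outer(rowSums(centers^2), rowSums(X^2), "+") - 2 * g
  d2[d2 < 0] <- 0
  sqrt(apply(d2, 1L, min))
}

## n approximately uniform unit vectors (Fibonacci sphere), deterministic.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stopf("cannot normalize a zero vector")
  v / n
}

## Orthonormal basis (3x3, columns) whose third column is `z`.
basis_from_z <- function(z) {
  z <- unit(z)
  ref <- if (abs(z[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- unit(ref - sum(ref * z) * z)
  y <- c(z[2L] * x[3L] - z[3L] * x[2L],
         z[3L] * x[1L] - z[1L] * x[3L],
         z[1L] * x[2L] - z[2L] * x[1L])
  cbind(x, y, z, deparse.level = 0)
}

## Deterministic spiral of n points inside a spherical cap of angular radius
## `ang` (radians) around direction `dir`, at radius R from the origin.
cap_points <- function(dir, n, ang, R) {
  B <- basis_from_z(dir)
  k <- seq_len(n)
  theta <- ang * sqrt((k - 0.5) / n)
  psi <- k * 2.399963                    # golden angle
  local <- cbind(sin(theta) * cos(psi), sin(theta) * sin(psi), cos(theta))
  R * local %*% t(B)
}

angular_dist <- function(u, v) acos(pmin(1, pmax(-1, sum(u * v))))

## Smoothstep interpolation weight on [0,1].
smoothstep <- function(s) {
  s <- pmin(1, pmax(0, s))
  s * s * (3 - 2 * s)
}

## Piecewise-smooth interpolation through keyframes.
## key_frames: increasing integer frames; key_pos: k x 3 positions.
## Returns n_frames x 3 path (constant before first / after last key).
interpolate_path <- function(key_frames, key_pos, n_frames) {
  stopifnot(length(key_frames) == nrow(key_pos))
  out <- matrix(NA_real_, n_frames, 3L)
  kf <- key_frames
  out[seq_len(min(kf[1L], n_frames)), ] <- rep(key_pos[1L, ], each = min(kf[1L], n_frames))
  for (j in seq_len(length(kf) - 1L)) {
    a <- kf[j]; b <- kf[j + 1L]
    if (a >= n_frames) break
    idx <- seq(a, min(b, n_frames))
    s <- smoothstep((idx - a) / (b - a))
    out[idx, ] <- (1 - s) %o% key_pos[j, ] + s %o% key_pos[j + 1L, ]
  }
  last <- kf[length(kf)]
  if (last < n_frames) out[seq(last, n_frames), ] <- rep(key_pos[nrow(key_pos), ],
                                                         each = n_frames - last + 1L)
  out
}

## Tokenized key-value config reader: drops blanks and '#' comments, splits on
## whitespace. Returns list of character vectors.
read_config_lines <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) strsplit(l, "[[:space:]]+")[[1L]])
}

## Portal label from two helix labels: alphabetized, "B-G" never "G-B".
portal_label <- function(h1, h2) paste(sort(c(h1, h2)), collapse = "-")

## Compact run-length encoding as a data.frame of (value, start, end).
rle_runs <- function(x) {
  r <- rle(as.character(x))
  end <- cumsum(r$lengths)
  data.frame(value = r$values, start = end - r$lengths + 1L, end = end,
             length = r$lengths, stringsAsFactors = FALSE)
}
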