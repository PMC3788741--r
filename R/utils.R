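#' @useDynLib thromboflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif var approx fft coef lm
#' @importFrom utils read.csv write.csv modifyList
NULL

## ---- quaternions (scalar-first convention c(w, x, y, z)) ----

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Rotation matrix of a unit quaternion
#' @param q unit quaternion, scalar first
#' @return 3x3 rotation matrix
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Quaternion of a rotation vector (exponential map)
#' @param v rotation vector; angle |v| about v-hat
#' @return unit quaternion, scalar first
#' @export
quat_from_rotvec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-300) return(quat_identity())
  c(cos(th / 2), sin(th / 2) * v / th)
}

quat_random <- function() quat_normalize(rnorm(4))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## ---- octahedron-based sphere triangulation ----
## 8 * 4^k faces; k = 3 gives the 512-face collocation sphere.

#' Triangulated unit sphere from recursive octahedron subdivision
#'
#' Faces come in powers 8 * 4^k, so resolution is specified by the
#' subdivision level.  All vertices lie exactly on the unit sphere and the
#' mesh inherits the mirror symmetries of the octahedron.
#'
#' @param subdiv non-negative integer subdivision level
#' @return list with `vertices` (n x 3) and `triangles` (m x 3, 1-based)
#' @keywords internal
octasphere <- function(subdiv = 3) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (s in seq_len(subdiv)) {
    edge_key <- function(i, j) paste(min(i, j), max(i, j))
    midpoints <- new.env(hash = TRUE)
    newv <- list()
    nv <- nrow(v)
    get_mid <- function(i, j) {
      k <- edge_key(i, j)
      if (!is.null(midpoints[[k]])) return(midpoints[[k]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      idx <- nv + length(newv)
      midpoints[[k]] <- idx
      idx
    }
    newf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (t in seq_len(nrow(f))) {
      i <- f[t, 1]; j <- f[t, 2]; k <- f[t, 3]
      a <- get_mid(i, j); b <- get_mid(j, k); cc <- get_mid(k, i)
      newf[4 * t - 3, ] <- c(i, a, cc)
      newf[4 * t - 2, ] <- c(a, j, b)
      newf[4 * t - 1, ] <- c(cc, b, k)
      newf[4 * t, ] <- c(a, b, cc)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  list(vertices = v, triangles = f)
}

## ---- small dense GMRES with optional right preconditioner ----

#' Restarted GMRES for dense operators
#'
#' @param amul function(x) returning A %*% x
#' @param b right-hand side
#' @param precond function(x) applying an approximate inverse (right
#'   preconditioning); identity if NULL
#' @param tol relative residual target
#' @param max_iter maximum total iterations
#' @param restart restart length
#' @return list(x, residual, iterations, converged)
#' @keywords internal
gmres_solve <- function(amul, b, precond = NULL, tol = 1e-6,
                        max_iter = 300, restart = 120) {
  if (is.null(precond)) precond <- identity
  n <- length(b)
  x <- numeric(n)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, residual = 0, iterations = 0L,
                              converged = TRUE))
  total_it <- 0L
  repeat {
    r <- b - amul(x)
    beta <- sqrt(sum(r^2))
    if (beta / bnorm <= tol || total_it >= max_iter)
      return(list(x = x, residual = beta / bnorm, iterations = total_it,
                  converged = beta / bnorm <= tol))
    m <- min(restart, max_iter - total_it)
    V <- matrix(0, n, m + 1)
    H <- matrix(0, m + 1, m)
    cs <- numeric(m); sn <- numeric(m)
    g <- numeric(m + 1); g[1] <- beta
    V[, 1] <- r / beta
    k_used <- 0L
    for (k in seq_len(m)) {
      w <- amul(precond(V[, k]))
      for (i in seq_len(k)) {            # modified Gram-Schmidt
        H[i, k] <- sum(w * V[, i])
        w <- w - H[i, k] * V[, i]
      }
      H[k + 1, k] <- sqrt(sum(w^2))
      if (H[k + 1, k] > 1e-14) V[, k + 1] <- w / H[k + 1, k]
      for (i in seq_len(k - 1)) {        # apply stored Givens rotations
        t1 <- cs[i] * H[i, k] + sn[i] * H[i + 1, k]
        H[i + 1, k] <- -sn[i] * H[i, k] + cs[i] * H[i + 1, k]
        H[i, k] <- t1
      }
      d <- sqrt(H[k, k]^2 + H[k + 1, k]^2)
      cs[k] <- H[k, k] / d; sn[k] <- H[k + 1, k] / d
      H[k, k] <- d; H[k + 1, k] <- 0
      g[k + 1] <- -sn[k] * g[k]
      g[k] <- cs[k] * g[k]
      k_used <- k
      total_it <- total_it + 1L
      if (abs(g[k + 1]) / bnorm <= tol) break
    }
    y <- backsolve(H[seq_len(k_used), seq_len(k_used), drop = FALSE],
                   g[seq_len(k_used)])
    x <- x + precond(V[, seq_len(k_used), drop = FALSE] %*% y)
    if (abs(g[k_used + 1]) / bnorm <= tol && total_it < max_iter) {
      r <- b - amul(x)
      res <- sqrt(sum(r^2)) / bnorm
      return(list(x = x, residual = res, iterations = total_it,
                  converged = res <= 10 * tol))
    }
  }
}

## ---- misc ----

## FNV-1a hash of a character string, reported as 8 hex digits.
fnv1a_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
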