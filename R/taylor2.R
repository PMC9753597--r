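# Second-order forward-mode differentiation used to obtain exact Wilson B
# rows and B' blocks.  A `t2` value carries (value, gradient, Hessian) with
# respect to the Cartesian coordinates of the few atoms defining one internal
# coordinate, propagated through truncated second-order Taylor arithmetic.
# This keeps the derivative code in one place and exact to machine precision
# for every coordinate kind, including the linear-angle pair.

.t2 <- function(v, g, H) list(v = v, g = g, H = H)

.t2_const <- function(v, n) .t2(v, numeric(n), matrix(0, n, n))

.t2_var <- function(v, i, n) {
  g <- numeric(n); g[i] <- 1
  .t2(v, g, matrix(0, n, n))
}

.t2_add <- function(a, b) .t2(a$v + b$v, a$g + b$g, a$H + b$H)
.t2_sub <- function(a, b) .t2(a$v - b$v, a$g - b$g, a$H - b$H)
.t2_neg <- function(a) .t2(-a$v, -a$g, -a$H)

.t2_mul <- function(a, b) {
  .t2(a$v * b$v,
      a$v * b$g + b$v * a$g,
      a$v * b$H + b$v * a$H + outer(a$g, b$g) + outer(b$g, a$g))
}

.t2_scale <- function(a, s) .t2(s * a$v, s * a$g, s * a$H)

## univariate chain rule: f(a) with f' and f''
.t2_chain <- function(a, f, fp, fpp) {
  .t2(f, fp * a$g, fp * a$H + fpp * outer(a$g, a$g))
}

.t2_inv <- function(a) .t2_chain(a, 1 / a$v, -1 / a$v^2, 2 / a$v^3)
.t2_div <- function(a, b) .t2_mul(a, .t2_inv(b))
.t2_sqrt <- function(a) {
  s <- sqrt(a$v)
  .t2_chain(a, s, 0.5 / s, -0.25 / s^3)
}

## atan2(y, x) for t2 arguments: d atan2 = (x dy - y dx) / r2
.t2_atan2 <- function(y, x) {
  r2 <- x$v^2 + y$v^2
  v <- atan2(y$v, x$v)
  gx <- -y$v / r2; gy <- x$v / r2
  g <- gx * x$g + gy * y$g
  # second derivatives of atan2 w.r.t. (x, y)
  hxx <- 2 * x$v * y$v / r2^2
  hyy <- -hxx
  hxy <- (y$v^2 - x$v^2) / r2^2
  H <- gx * x$H + gy * y$H +
    hxx * outer(x$g, x$g) + hyy * outer(y$g, y$g) +
    hxy * (outer(x$g, y$g) + outer(y$g, x$g))
  .t2(v, g, H)
}

## 3-vectors of t2 scalars -------------------------------------------------
.t2_vec <- function(xvals, offset, n) {
  lapply(1:3, function(k) .t2_var(xvals[k], offset + k, n))
}

.t2_vdiff <- function(a, b) Map(.t2_sub, a, b)

.t2_dot <- function(a, b) {
  .t2_add(.t2_add(.t2_mul(a[[1]], b[[1]]), .t2_mul(a[[2]], b[[2]])),
          .t2_mul(a[[3]], b[[3]]))
}

.t2_cross <- function(a, b) {
  list(.t2_sub(.t2_mul(a[[2]], b[[3]]), .t2_mul(a[[3]], b[[2]])),
       .t2_sub(.t2_mul(a[[3]], b[[1]]), .t2_mul(a[[1]], b[[3]])),
       .t2_sub(.t2_mul(a[[1]], b[[2]]), .t2_mul(a[[2]], b[[1]])))
}

.t2_norm <- function(a) .t2_sqrt(.t2_dot(a, a))

.t2_vscale <- function(a, s) lapply(a, function(e) .t2_mul(e, s))

.t2_unit <- function(a) .t2_vscale(a, .t2_inv(.t2_norm(a)))

.t2_vadd <- function(a, b) Map(.t2_add, a, b)

.t2_vconst <- function(v, n) lapply(1:3, function(k) .t2_const(v[k], n))
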