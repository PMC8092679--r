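// Core geometry, topology and Monte-Carlo kernels for the discrete
// self-avoiding rod-like chain (sRLC).  All coordinates are in nm.
//
// The chain is a closed (or optionally open) polygon of N vertices; segment
// i joins vertex i to vertex (i+1) mod N.  Writhe is computed from the
// closed-form Gauss-integral contribution of straight segment pairs
// (Klenin & Langowski 2000, method 1a); adjacent segment pairs contribute
// exactly zero and are skipped.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1]*b[2] - a[2]*b[1];
  o[1] = a[2]*b[0] - a[0]*b[2];
  o[2] = a[0]*b[1] - a[1]*b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }
static inline double clamp1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}
static inline double clamp01(double x) {
  return x > 1.0 ? 1.0 : (x < 0.0 ? 0.0 : x);
}

// Gauss-integral contribution Omega of two straight segments p1->p2, p3->p4.
// Wr = sum over unordered non-adjacent pairs of Omega / (2*pi).
// Degenerate configurations (coplanar shared-endpoint cases) return 0.
static double seg_omega(const double* p1, const double* p2,
                        const double* p3, const double* p4) {
  double r12[3], r34[3], r13[3], r14[3], r23[3], r24[3];
  for (int k = 0; k < 3; ++k) {
    r12[k] = p2[k] - p1[k];  r34[k] = p4[k] - p3[k];
    r13[k] = p3[k] - p1[k];  r14[k] = p4[k] - p1[k];
    r23[k] = p3[k] - p2[k];  r24[k] = p4[k] - p2[k];
  }
  double n1[3], n2[3], n3[3], n4[3];
  cross3(r13, r14, n1); cross3(r14, r24, n2);
  cross3(r24, r23, n3); cross3(r23, r13, n4);
  double l1 = norm3(n1), l2 = norm3(n2), l3 = norm3(n3), l4 = norm3(n4);
  const double eps = 1e-12;
  if (l1 < eps || l2 < eps || l3 < eps || l4 < eps) return 0.0;
  for (int k = 0; k < 3; ++k) { n1[k]/=l1; n2[k]/=l2; n3[k]/=l3; n4[k]/=l4; }
  double om = std::asin(clamp1(dot3(n1, n2))) + std::asin(clamp1(dot3(n2, n3)))
            + std::asin(clamp1(dot3(n3, n4))) + std::asin(clamp1(dot3(n4, n1)));
  double cr[3];
  cross3(r34, r12, cr);
  double sg = dot3(cr, r13);
  return om * ((sg > 0.0) - (sg < 0.0));
}

// Minimum distance between segments [p1,p2] and [q1,q2] (Ericson, RTCD 5.1.9).
static double seg_dist(const double* p1, const double* p2,
                       const double* q1, const double* q2) {
  double d1[3], d2[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = p2[k] - p1[k]; d2[k] = q2[k] - q1[k]; r[k] = p1[k] - q1[k];
  }
  double a = dot3(d1, d1), e = dot3(d2, d2);
  double b = dot3(d1, d2), c = dot3(d1, r), f = dot3(d2, r);
  double s, t;
  double denom = a*e - b*b;
  if (denom > 1e-14) s = clamp01((b*f - c*e) / denom); else s = 0.0;
  t = (b*s + f) / e;
  if (t < 0.0)      { t = 0.0; s = clamp01(-c / a); }
  else if (t > 1.0) { t = 1.0; s = clamp01((b - c) / a); }
  double cp[3];
  for (int k = 0; k < 3; ++k)
    cp[k] = (p1[k] + s*d1[k]) - (q1[k] + t*d2[k]);
  return norm3(cp);
}

// ---- helpers on a row-major coordinate buffer ------------------------------

typedef std::vector<double> Coords; // length 3*N, row major

static Coords as_coords(const NumericMatrix& V) {
  int N = V.nrow();
  Coords P(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) P[3*i + k] = V(i, k);
  return P;
}
static NumericMatrix as_matrix(const Coords& P) {
  int N = (int)(P.size() / 3);
  NumericMatrix V(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) V(i, k) = P[3*i + k];
  return V;
}
static inline const double* vtx(const Coords& P, int i) { return &P[3*i]; }

// number of segments for a chain of N vertices
static inline int n_segments(int N, bool closed) { return closed ? N : N - 1; }

// are segments a and b adjacent (share a vertex) or identical?
static inline bool seg_adjacent(int a, int b, int S, bool closed) {
  int d = a - b; if (d < 0) d = -d;
  if (d <= 1) return true;
  if (closed && d == S - 1) return true;
  return false;
}

static double writhe_full(const Coords& P, int N, bool closed) {
  int S = n_segments(N, closed);
  double acc = 0.0;
  for (int a = 0; a < S; ++a) {
    const double* pa1 = vtx(P, a);
    const double* pa2 = vtx(P, (a + 1) % N);
    for (int b = a + 2; b < S; ++b) {
      if (closed && a == 0 && b == S - 1) continue; // adjacent across the seam
      acc += seg_omega(pa1, pa2, vtx(P, b), vtx(P, (b + 1) % N));
    }
  }
  return acc / (2.0 * M_PI);
}

// bending energy sum_joints kappa * (1 - cos theta)
static double bending_full(const Coords& P, int N, double kappa, bool closed) {
  double acc = 0.0;
  int j0 = closed ? 0 : 1, j1 = closed ? N : N - 1;
  for (int v = j0; v < j1; ++v) {
    int vp = (v - 1 + N) % N;
    double dp[3], dn[3];
    for (int k = 0; k < 3; ++k) {
      dp[k] = P[3*v + k] - P[3*vp + k];
      dn[k] = P[3*((v + 1) % N) + k] - P[3*v + k];
    }
    acc += 1.0 - dot3(dp, dn) / (norm3(dp) * norm3(dn));
  }
  return kappa * acc;
}

// cos of the joint angle at vertex v
static double joint_cos(const Coords& P, int N, int v) {
  int vp = (v - 1 + N) % N, vn = (v + 1) % N;
  double dp[3], dn[3];
  for (int k = 0; k < 3; ++k) {
    dp[k] = P[3*v + k] - P[3*vp + k];
    dn[k] = P[3*vn + k] - P[3*v + k];
  }
  return dot3(dp, dn) / (norm3(dp) * norm3(dn));
}

// ---- exported primitives ---------------------------------------------------

// [[Rcpp::export]]
double cpp_writhe(const NumericMatrix& V, bool closed = true) {
  return writhe_full(as_coords(V), V.nrow(), closed);
}

// [[Rcpp::export]]
double cpp_seg_omega(const NumericVector& p1, const NumericVector& p2,
                     const NumericVector& p3, const NumericVector& p4) {
  return seg_omega(&p1[0], &p2[0], &p3[0], &p4[0]);
}

// [[Rcpp::export]]
NumericVector cpp_local_writhe(const NumericMatrix& V, int m, bool closed = true) {
  Coords P = as_coords(V);
  int N = V.nrow();
  int S = n_segments(N, closed);
  NumericVector wr(S);
  bool full = (m + 1 >= S);
  for (int i = 0; i < S; ++i) {
    double acc = 0.0;
    if (full) {
      for (int j = 0; j < S; ++j) {
        if (seg_adjacent(i, j, S, closed)) continue;
        acc += seg_omega(vtx(P, i), vtx(P, (i + 1) % N),
                         vtx(P, j), vtx(P, (j + 1) % N));
      }
    } else {
      for (int off = -m / 2; off <= m / 2; ++off) {
        if (off == 0) continue;
        int j = i + off;
        if (closed) j = (j % S + S) % S; else if (j < 0 || j >= S) continue;
        if (seg_adjacent(i, j, S, closed)) continue;
        acc += seg_omega(vtx(P, i), vtx(P, (i + 1) % N),
                         vtx(P, j), vtx(P, (j + 1) % N));
      }
    }
    wr[i] = acc / (2.0 * M_PI);
  }
  return wr;
}

// [[Rcpp::export]]
double cpp_min_nonadjacent_dist(const NumericMatrix& V, bool closed = true) {
  Coords P = as_coords(V);
  int N = V.nrow(), S = n_segments(N, closed);
  double best = R_PosInf;
  for (int a = 0; a < S; ++a)
    for (int b = a + 2; b < S; ++b) {
      if (closed && a == 0 && b == S - 1) continue;
      double d = seg_dist(vtx(P, a), vtx(P, (a + 1) % N),
                          vtx(P, b), vtx(P, (b + 1) % N));
      if (d < best) best = d;
    }
  return best;
}

// moved_lo/moved_hi: 0-based inclusive segment range (may wrap, lo > hi);
// negative values check every non-adjacent pair.
// [[Rcpp::export]]
bool cpp_check_self_avoidance(const NumericMatrix& V, double min_dist,
                              bool closed = true,
                              int moved_lo = -1, int moved_hi = -1) {
  Coords P = as_coords(V);
  int N = V.nrow(), S = n_segments(N, closed);
  if (moved_lo < 0) {
    for (int a = 0; a < S; ++a)
      for (int b = a + 2; b < S; ++b) {
        if (closed && a == 0 && b == S - 1) continue;
        if (seg_dist(vtx(P, a), vtx(P, (a + 1) % N),
                     vtx(P, b), vtx(P, (b + 1) % N)) < min_dist) return false;
      }
    return true;
  }
  std::vector<char> moved(S, 0);
  for (int a = moved_lo; ; a = (a + 1) % S) {
    moved[a] = 1;
    if (a == moved_hi) break;
  }
  for (int a = 0; a < S; ++a) {
    if (!moved[a]) continue;
    for (int b = 0; b < S; ++b) {
      if (moved[b] && b <= a) continue; // moved-moved pairs once; skip a==b
      if (seg_adjacent(a, b, S, closed)) continue;
      if (seg_dist(vtx(P, a), vtx(P, (a + 1) % N),
                   vtx(P, b), vtx(P, (b + 1) % N)) < min_dist) return false;
    }
  }
  return true;
}

// [[Rcpp::export]]
double cpp_bending_energy(const NumericMatrix& V, double kappa, bool closed = true) {
  return bending_full(as_coords(V), V.nrow(), kappa, closed);
}

// Rigidly rotate vertices strictly between vertex i and vertex j = i + span
// (0-based i) about the i--j axis by `angle` radians.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_block(const NumericMatrix& V, int i, int span,
                               double angle, bool closed = true) {
  Coords P = as_coords(V);
  int N = V.nrow();
  int j = closed ? (i + span) % N : i + span;
  const double* pi_ = vtx(P, i);
  const double* pj_ = vtx(P, j);
  double u[3];
  for (int k = 0; k < 3; ++k) u[k] = pj_[k] - pi_[k];
  double un = norm3(u);
  if (un < 1e-14) stop("degenerate rotation axis (coincident pivot vertices)");
  for (int k = 0; k < 3; ++k) u[k] /= un;
  double ca = std::cos(angle), sa = std::sin(angle);
  double o[3] = { pi_[0], pi_[1], pi_[2] };
  for (int t = 1; t < span; ++t) {
    int v = closed ? (i + t) % N : i + t;
    double x[3], ux[3];
    for (int k = 0; k < 3; ++k) x[k] = P[3*v + k] - o[k];
    double ud = dot3(u, x);
    cross3(u, x, ux);
    for (int k = 0; k < 3; ++k)
      P[3*v + k] = o[k] + x[k]*ca + ux[k]*sa + u[k]*ud*(1.0 - ca);
  }
  return as_matrix(P);
}

// ---- Metropolis crankshaft engine ------------------------------------------
//
// One sweep = moves_per_sweep crankshaft attempts.  sigma (i.e. Lk) is held
// fixed throughout; the twist deficit is bookkept as (Lk - Lk0) - Wr and the
// torsional energy is the uniform-twist form c_tw * dTw^2 with
// c_tw = 2 * pi^2 * C / L.  Writhe is updated incrementally from moved vs
// unmoved segment pairs and fully recomputed every `full_every` accepted
// moves to guard against numerical drift.  Moves whose writhe jump exceeds
// wr_jump_max (signature of a strand passage) are rejected, as are moves
// creating a hard-core overlap.  Uses R's RNG stream.

// [[Rcpp::export]]
List cpp_run_sweeps(const NumericMatrix& V0, double Lk, double Lk0,
                    double kappa, double c_tw, double min_dist,
                    int M, double max_angle,
                    int n_sweeps, int moves_per_sweep,
                    bool self_avoid, bool closed, bool torsion,
                    double wr_jump_max, int full_every,
                    IntegerVector record_at, bool per_sweep_diag) {
  Coords P = as_coords(V0);
  int N = V0.nrow();
  int S = n_segments(N, closed);
  if (M > N - 2) stop("M must be <= N - 2");
  double dLk = Lk - Lk0;
  bool track_wr = closed && (torsion || wr_jump_max < R_PosInf);
  double Wr = track_wr ? writhe_full(P, N, closed) : 0.0;

  long accepted = 0, attempted = 0;
  long rej_overlap = 0, rej_wrjump = 0, rej_metropolis = 0;
  long acc_since_full = 0;

  std::vector<char> moved_seg(S, 0);
  Coords Pold;

  List frames;
  std::vector<double> frame_wr;
  std::vector<int> frame_sweep;
  int rec_ptr = 0, n_rec = record_at.size();

  std::vector<double> sw_wr, sw_ebend, sw_acc;
  if (per_sweep_diag) {
    sw_wr.reserve(n_sweeps); sw_ebend.reserve(n_sweeps); sw_acc.reserve(n_sweeps);
  }

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    long acc_this_sweep = 0;
    for (int mv = 0; mv < moves_per_sweep; ++mv) {
      ++attempted;
      int i, span, j;
      double axis[3];
      bool pivot_move = !closed;
      double angle = 0.0;
      if (closed) {
        // crankshaft: rotate the block strictly between vertices i and j
        // about the i--j axis
        i = (int)(unif_rand() * N); if (i >= N) i = N - 1;
        span = 1 + (int)(unif_rand() * M); if (span > M) span = M;
        angle = (2.0 * unif_rand() - 1.0) * max_angle;
        if (span < 2) { ++accepted; ++acc_this_sweep; continue; } // no-op
        j = (i + span) % N;
      } else {
        // open chain: suffix-pivot move (rotate vertices i+1..N-1 about a
        // uniformly random axis through vertex i).  Crankshaft alone pins
        // the chain ends; pivot moves are ergodic and exactly preserve the
        // product-of-spheres measure on bond directions.
        i = 1 + (int)(unif_rand() * (N - 2)); if (i > N - 2) i = N - 2;
        double z = 2.0 * unif_rand() - 1.0;
        double phi = 2.0 * M_PI * unif_rand();
        double sz = std::sqrt(std::max(0.0, 1.0 - z * z));
        axis[0] = sz * std::cos(phi); axis[1] = sz * std::sin(phi); axis[2] = z;
        angle = (2.0 * unif_rand() - 1.0) * max_angle;
        span = N - 1 - i;  // vertices i+1..N-1 move
        j = N - 1;
      }

      // joints whose angle changes (pivot vertices only; the block is rigid)
      double cos_i_old = 0.0, cos_j_old = 0.0;
      bool ji_ok = closed || (i >= 1);
      bool jj_ok = closed && true;
      if (ji_ok) cos_i_old = joint_cos(P, N, i);
      if (jj_ok) cos_j_old = joint_cos(P, N, j);

      // moved segments: i .. i+span-1 (mod S); for the pivot move these are
      // the suffix segments i..S-1
      int lo = i % S, hi = (i + span - 1) % S;
      for (int a = lo; ; a = (a + 1) % S) { moved_seg[a] = 1; if (a == hi) break; }

      double om_old = 0.0;
      if (track_wr) {
        for (int a = lo; ; a = (a + 1) % S) {
          const double* a1 = vtx(P, a);
          const double* a2 = vtx(P, (a + 1) % N);
          for (int b = 0; b < S; ++b) {
            if (moved_seg[b]) continue;
            if (seg_adjacent(a, b, S, closed)) continue;
            om_old += seg_omega(a1, a2, vtx(P, b), vtx(P, (b + 1) % N));
          }
          if (a == hi) break;
        }
      }

      // rotate (keep a rollback copy)
      Pold = P;
      {
        const double* pi_ = vtx(P, i);
        double u[3];
        if (pivot_move) {
          u[0] = axis[0]; u[1] = axis[1]; u[2] = axis[2];
        } else {
          const double* pj_ = vtx(P, j);
          for (int k = 0; k < 3; ++k) u[k] = pj_[k] - pi_[k];
          double un = norm3(u);
          for (int k = 0; k < 3; ++k) u[k] /= un;
        }
        double ca = std::cos(angle), sa = std::sin(angle);
        double o[3] = { pi_[0], pi_[1], pi_[2] };
        int t_last = pivot_move ? span : span - 1;
        for (int t = 1; t <= t_last; ++t) {
          int v = closed ? (i + t) % N : i + t;
          double x[3], ux[3];
          for (int k = 0; k < 3; ++k) x[k] = P[3*v + k] - o[k];
          double ud = dot3(u, x);
          cross3(u, x, ux);
          for (int k = 0; k < 3; ++k)
            P[3*v + k] = o[k] + x[k]*ca + ux[k]*sa + u[k]*ud*(1.0 - ca);
        }
      }

      bool reject = false;

      // hard core: moved segments vs unmoved non-adjacent segments
      if (self_avoid) {
        for (int a = lo; !reject; a = (a + 1) % S) {
          const double* a1 = vtx(P, a);
          const double* a2 = vtx(P, (a + 1) % N);
          for (int b = 0; b < S; ++b) {
            if (moved_seg[b]) continue;
            if (seg_adjacent(a, b, S, closed)) continue;
            if (seg_dist(a1, a2, vtx(P, b), vtx(P, (b + 1) % N)) < min_dist) {
              reject = true; ++rej_overlap; break;
            }
          }
          if (a == hi) break;
        }
      }

      double dWr = 0.0;
      if (!reject && track_wr) {
        double om_new = 0.0;
        for (int a = lo; ; a = (a + 1) % S) {
          const double* a1 = vtx(P, a);
          const double* a2 = vtx(P, (a + 1) % N);
          for (int b = 0; b < S; ++b) {
            if (moved_seg[b]) continue;
            if (seg_adjacent(a, b, S, closed)) continue;
            om_new += seg_omega(a1, a2, vtx(P, b), vtx(P, (b + 1) % N));
          }
          if (a == hi) break;
        }
        dWr = (om_new - om_old) / (2.0 * M_PI);
        if (std::fabs(dWr) > wr_jump_max) { reject = true; ++rej_wrjump; }
      }

      if (!reject) {
        double dE = 0.0;
        if (ji_ok) dE += kappa * (cos_i_old - joint_cos(P, N, i));
        if (jj_ok) dE += kappa * (cos_j_old - joint_cos(P, N, j));
        if (torsion) {
          double dTw_old = dLk - Wr, dTw_new = dLk - (Wr + dWr);
          dE += c_tw * (dTw_new * dTw_new - dTw_old * dTw_old);
        }
        if (!std::isfinite(dE)) stop("non-finite energy change in MC sweep");
        if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
          ++accepted; ++acc_this_sweep;
          Wr += dWr;
          if (track_wr && ++acc_since_full >= full_every) {
            Wr = writhe_full(P, N, closed);
            acc_since_full = 0;
          }
        } else { reject = true; ++rej_metropolis; }
      }

      if (reject) P = Pold;

      for (int a = lo; ; a = (a + 1) % S) { moved_seg[a] = 0; if (a == hi) break; }
    }

    if (per_sweep_diag) {
      sw_wr.push_back(track_wr ? Wr : NA_REAL);
      sw_ebend.push_back(bending_full(P, N, kappa, closed));
      sw_acc.push_back((double)acc_this_sweep / moves_per_sweep);
    }
    if (rec_ptr < n_rec && record_at[rec_ptr] == sweep) {
      if (track_wr) { Wr = writhe_full(P, N, closed); acc_since_full = 0; }
      frames.push_back(as_matrix(P));
      frame_wr.push_back(track_wr ? Wr : NA_REAL);
      frame_sweep.push_back(sweep);
      ++rec_ptr;
    }
  }

  if (track_wr) Wr = writhe_full(P, N, closed);

  return List::create(
    _["vertices"] = as_matrix(P),
    _["Wr"] = track_wr ? Wr : NA_REAL,
    _["accepted"] = (double)accepted,
    _["attempted"] = (double)attempted,
    _["rej_overlap"] = (double)rej_overlap,
    _["rej_wrjump"] = (double)rej_wrjump,
    _["rej_metropolis"] = (double)rej_metropolis,
    _["frames"] = frames,
    _["frame_wr"] = NumericVector(frame_wr.begin(), frame_wr.end()),
    _["frame_sweep"] = IntegerVector(frame_sweep.begin(), frame_sweep.end()),
    _["sweep_wr"] = NumericVector(sw_wr.begin(), sw_wr.end()),
    _["sweep_ebend"] = NumericVector(sw_ebend.begin(), sw_ebend.end()),
    _["sweep_acc"] = NumericVector(sw_acc.begin(), sw_acc.end()));
}
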