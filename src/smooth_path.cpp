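#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p (Ericson, Real-Time Collision
// Detection). Writes the result into out[3], returns squared distance.
static double closestPointTri(const double *p, const double *a,
                              const double *b, const double *c,
                              double *out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
  } else {
    double bp[3];
    for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      for (int k = 0; k < 3; ++k) out[k] = b[k];
    } else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
      } else {
        double cp[3];
        for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
        double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
        double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          for (int k = 0; k < 3; ++k) out[k] = c[k];
        } else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k = 0; k < 3; ++k)
                out[k] = b[k] + w * (c[k] - b[k]);
            } else {
              double denom = va + vb + vc;
              double v = vb / denom, w = vc / denom;
              for (int k = 0; k < 3; ++k)
                out[k] = a[k] + ab[k] * v + ac[k] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0]-out[0], dy = p[1]-out[1], dz = p[2]-out[2];
  return dx*dx + dy*dy + dz*dz;
}

struct MeshRef {
  const double *V; int nv;
  const int *F; int nf;           // 0-based, column-major nf x 3
  const int *adjPtr, *adjIdx;     // CSR: faces adjacent (vertex-sharing) per face
  double tri(int f, int corner, int k) const {
    int vid = F[f + (size_t)corner * nf];
    return V[vid + (size_t)k * nv];
  }
};

// Project p onto the mesh near face f0 by hill-climbing over vertex-sharing
// face neighborhoods; updates *face, writes foot point into out.
static double projectLocal(const MeshRef &M, const double *p, int *face,
                           double *out) {
  int cur = *face;
  double best[3], cand[3];
  double a[3], b[3], c[3];
  for (int k = 0; k < 3; ++k) { a[k]=M.tri(cur,0,k); b[k]=M.tri(cur,1,k); c[k]=M.tri(cur,2,k); }
  double bestD = closestPointTri(p, a, b, c, best);
  for (int hop = 0; hop < 12; ++hop) {
    int improvedFace = -1;
    for (int j = M.adjPtr[cur]; j < M.adjPtr[cur + 1]; ++j) {
      int f = M.adjIdx[j];
      for (int k = 0; k < 3; ++k) { a[k]=M.tri(f,0,k); b[k]=M.tri(f,1,k); c[k]=M.tri(f,2,k); }
      double d = closestPointTri(p, a, b, c, cand);
      if (d < bestD - 1e-30) {
        bestD = d; improvedFace = f;
        best[0]=cand[0]; best[1]=cand[1]; best[2]=cand[2];
      }
    }
    if (improvedFace < 0) break;
    cur = improvedFace;
  }
  *face = cur;
  out[0]=best[0]; out[1]=best[1]; out[2]=best[2];
  return bestD;
}

// Geodesic-shortening flow: interior path points move toward the midpoint
// of their neighbours (with over-relaxation) and are re-projected onto the
// mesh, until the largest move falls below tol. The fixed point is a
// discrete geodesic, independent of the Dijkstra corridor the path came
// from. Red-black ordering keeps sweeps consistent.
// [[Rcpp::export]]
List smooth_path_cpp(NumericMatrix path, IntegerVector faceOf,
                     NumericMatrix V, IntegerMatrix F,
                     IntegerVector adjPtr, IntegerVector adjIdx,
                     double omega, int maxSweeps, double tol) {
  int m = path.nrow();
  NumericMatrix P = clone(path);
  std::vector<int> face(faceOf.begin(), faceOf.end());
  MeshRef M;
  M.V = REAL(V); M.nv = V.nrow();
  M.F = INTEGER(F); M.nf = F.nrow();
  M.adjPtr = INTEGER(adjPtr); M.adjIdx = INTEGER(adjIdx);
  if (m <= 2)
    return List::create(_["points"] = P, _["faces"] = faceOf);
  double tol2 = tol * tol;
  double *pp = REAL(P);
  int nrow = m;
  double prevLen = -1.0;
  for (int sweep = 0; sweep < maxSweeps; ++sweep) {
    double maxMove2 = 0.0;
    for (int parity = 1; parity <= 2; ++parity) {
      for (int i = parity; i < m - 1; i += 2) {
        double tgt[3], q[3], cur[3];
        for (int k = 0; k < 3; ++k) {
          double mid = 0.5 * (pp[(i-1) + (size_t)k*nrow] +
                              pp[(i+1) + (size_t)k*nrow]);
          cur[k] = pp[i + (size_t)k*nrow];
          tgt[k] = cur[k] + omega * (mid - cur[k]);
        }
        int f = face[i];
        projectLocal(M, tgt, &f, q);
        face[i] = f;
        double d2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          double dk = q[k] - cur[k];
          d2 += dk * dk;
          pp[i + (size_t)k*nrow] = q[k];
        }
        if (d2 > maxMove2) maxMove2 = d2;
      }
    }
    if (maxMove2 < tol2) break;
    // tangential sliding can keep points moving long after the curve has
    // geometrically converged; stop once the length is stationary
    if ((sweep & 31) == 31) {
      double L = 0.0;
      for (int i = 1; i < m; ++i) {
        double d2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          double dk = pp[i + (size_t)k*nrow] - pp[(i-1) + (size_t)k*nrow];
          d2 += dk * dk;
        }
        L += std::sqrt(d2);
      }
      if (prevLen >= 0.0 && std::fabs(prevLen - L) < 1e-11 * L) break;
      prevLen = L;
    }
  }
  IntegerVector outFace(face.begin(), face.end());
  return List::create(_["points"] = P, _["faces"] = outFace);
}
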