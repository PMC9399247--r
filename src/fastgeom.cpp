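#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// Compact 3-d kd-tree over a fixed point set; leaves hold <= 8 points.
struct KD3 {
  std::vector<double> P;
  std::vector<int> id;
  struct Node { int lo, hi, ax, l, r; double sp; };
  std::vector<Node> nodes;
  int n;

  explicit KD3(const NumericMatrix& M) : n(M.nrow()) {
    P.resize(3 * (size_t)n); id.resize(n);
    for (int i = 0; i < n; ++i) {
      P[3*i] = M(i,0); P[3*i+1] = M(i,1); P[3*i+2] = M(i,2);
      id[i] = i;
    }
    nodes.reserve((size_t)n / 4 + 8);
    build(0, n);
  }

  int build(int lo, int hi) {
    int me = (int)nodes.size();
    nodes.push_back({lo, hi, -1, -1, -1, 0.0});
    if (hi - lo <= 8) return me;
    double mn[3] = {R_PosInf, R_PosInf, R_PosInf};
    double mx[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = lo; i < hi; ++i)
      for (int a = 0; a < 3; ++a) {
        double v = P[3*id[i]+a];
        if (v < mn[a]) mn[a] = v;
        if (v > mx[a]) mx[a] = v;
      }
    int ax = 0; double w = mx[0] - mn[0];
    for (int a = 1; a < 3; ++a) if (mx[a] - mn[a] > w) { w = mx[a] - mn[a]; ax = a; }
    int mid = (lo + hi) / 2;
    const double* PP = P.data();
    std::nth_element(id.begin()+lo, id.begin()+mid, id.begin()+hi,
                     [PP, ax](int a, int b){ return PP[3*a+ax] < PP[3*b+ax]; });
    nodes[me].ax = ax;
    nodes[me].sp = P[3*id[mid]+ax];
    int l = build(lo, mid), r = build(mid, hi);
    nodes[me].l = l; nodes[me].r = r;
    return me;
  }

  void query(const double* q, int node, double& best, int& bi) const {
    const Node& nd = nodes[node];
    if (nd.ax < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int j = id[i];
        double dx = q[0]-P[3*j], dy = q[1]-P[3*j+1], dz = q[2]-P[3*j+2];
        double d = dx*dx + dy*dy + dz*dz;
        if (d < best) { best = d; bi = j; }
      }
      return;
    }
    double diff = q[nd.ax] - nd.sp;
    int first  = diff < 0 ? nd.l : nd.r;
    int second = diff < 0 ? nd.r : nd.l;
    query(q, first, best, bi);
    if (diff * diff < best) query(q, second, best, bi);
  }
};

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection).
// Writes the closest point to out[3] and barycentric (w.r.t. a,b,c) to w[3].
void closest_pt_tri(const double* p, const double* a, const double* b,
                    const double* c, double* out, double* w) {
  double ab[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double ac[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double ap[3] = {p[0]-a[0], p[1]-a[1], p[2]-a[2]};
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; w[0]=1; w[1]=0; w[2]=0; return;
  }
  double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; w[0]=0; w[1]=1; w[2]=0; return;
  }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k=0;k<3;++k) out[k] = a[k] + v*ab[k];
    w[0]=1-v; w[1]=v; w[2]=0; return;
  }
  double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; w[0]=0; w[1]=0; w[2]=1; return;
  }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double v = d2 / (d2 - d6);
    for (int k=0;k<3;++k) out[k] = a[k] + v*ac[k];
    w[0]=1-v; w[1]=0; w[2]=v; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double v = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k=0;k<3;++k) out[k] = b[k] + v*(c[k]-b[k]);
    w[0]=0; w[1]=1-v; w[2]=v; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, u = vc * denom;
  for (int k=0;k<3;++k) out[k] = a[k] + ab[k]*v + ac[k]*u;
  w[0]=1-v-u; w[1]=v; w[2]=u;
}

} // namespace

static List kd_query_impl(const KD3& tree, const NumericMatrix& query) {
  int m = query.nrow();
  IntegerVector idx(m);
  NumericVector dist(m);
  for (int i = 0; i < m; ++i) {
    double q[3] = {query(i,0), query(i,1), query(i,2)};
    double best = R_PosInf; int bi = -1;
    tree.query(q, 0, best, bi);
    idx[i] = bi + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

static List kd_hausdorff_impl(const KD3& tree, const NumericMatrix& A) {
  double worst = -1.0; int wi = -1;
  int n = A.nrow();
  for (int i = 0; i < n; ++i) {
    double q[3] = {A(i,0), A(i,1), A(i,2)};
    double best = R_PosInf; int bi = -1;
    tree.query(q, 0, best, bi);
    if (best > worst) { worst = best; wi = i; }
  }
  return List::create(_["distance"] = std::sqrt(worst), _["index"] = wi + 1);
}

// Nearest neighbour in `ref` for every row of `query`; 1-based indices.
// [[Rcpp::export]]
List cpp_nn(NumericMatrix ref, NumericMatrix query) {
  if (ref.nrow() < 1) stop("empty reference point set");
  KD3 tree(ref);
  return kd_query_impl(tree, query);
}

// Directed Hausdorff distance max_{a in A} min_{b in B} |a-b|.
// [[Rcpp::export]]
List cpp_directed_hausdorff(NumericMatrix A, NumericMatrix B) {
  if (A.nrow() < 1 || B.nrow() < 1) stop("empty point set");
  KD3 tree(B);
  return kd_hausdorff_impl(tree, A);
}

// Persistent kd-tree handle, reused across many queries against one set.
// [[Rcpp::export]]
SEXP cpp_kd_build(NumericMatrix pts) {
  if (pts.nrow() < 1) stop("empty point set");
  XPtr<KD3> p(new KD3(pts), true);
  return p;
}

// [[Rcpp::export]]
List cpp_kd_query(SEXP tree, NumericMatrix query) {
  XPtr<KD3> p(tree);
  return kd_query_impl(*p, query);
}

// Directed Hausdorff from A to the point set held by `tree`.
// [[Rcpp::export]]
List cpp_kd_hausdorff(SEXP tree, NumericMatrix A) {
  if (A.nrow() < 1) stop("empty point set");
  XPtr<KD3> p(tree);
  return kd_hausdorff_impl(*p, A);
}

// Closest point on a triangle mesh (V: n x 3, F: m x 3 one-based) for each
// row of P. Returns projected points, face index, barycentric coords, dist.
// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  int nf = F.nrow(), np = P.nrow();
  if (nf < 1) stop("empty mesh");
  NumericMatrix out(np, 3), bary(np, 3);
  IntegerVector face(np);
  NumericVector dist(np);
  // Precompute per-face centroids + circumscribing radius for pruning.
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  std::vector<const double*> va(nf), vb(nf), vc(nf);
  std::vector<double> VV(3 * (size_t)V.nrow());
  for (int i = 0; i < V.nrow(); ++i) {
    VV[3*i] = V(i,0); VV[3*i+1] = V(i,1); VV[3*i+2] = V(i,2);
  }
  NumericMatrix C(nf, 3);
  for (int f = 0; f < nf; ++f) {
    int ia = F(f,0)-1, ib = F(f,1)-1, ic = F(f,2)-1;
    va[f] = &VV[3*ia]; vb[f] = &VV[3*ib]; vc[f] = &VV[3*ic];
    cx[f] = (va[f][0]+vb[f][0]+vc[f][0])/3.0;
    cy[f] = (va[f][1]+vb[f][1]+vc[f][1])/3.0;
    cz[f] = (va[f][2]+vb[f][2]+vc[f][2])/3.0;
    double r = 0.0;
    const double* vs[3] = {va[f], vb[f], vc[f]};
    for (int k = 0; k < 3; ++k) {
      double dx = vs[k][0]-cx[f], dy = vs[k][1]-cy[f], dz = vs[k][2]-cz[f];
      double d = std::sqrt(dx*dx+dy*dy+dz*dz);
      if (d > r) r = d;
    }
    rad[f] = r;
    C(f,0) = cx[f]; C(f,1) = cy[f]; C(f,2) = cz[f];
  }
  KD3 ctree(C);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i,0), P(i,1), P(i,2)};
    // Seed with nearest centroid, then scan faces whose lower bound beats it.
    double cbest = R_PosInf; int cf = -1;
    ctree.query(p, 0, cbest, cf);
    double o[3], w[3];
    closest_pt_tri(p, va[cf], vb[cf], vc[cf], o, w);
    double bd = 0; for (int k=0;k<3;++k){ double d=p[k]-o[k]; bd += d*d; }
    double best = bd; int bf = cf;
    double bo[3] = {o[0],o[1],o[2]}, bw[3] = {w[0],w[1],w[2]};
    double bdist = std::sqrt(best);
    for (int f = 0; f < nf; ++f) {
      double dx = p[0]-cx[f], dy = p[1]-cy[f], dz = p[2]-cz[f];
      double lb = std::sqrt(dx*dx+dy*dy+dz*dz) - rad[f];
      if (lb >= bdist) continue;
      closest_pt_tri(p, va[f], vb[f], vc[f], o, w);
      double d2 = 0; for (int k=0;k<3;++k){ double d=p[k]-o[k]; d2 += d*d; }
      if (d2 < best) {
        best = d2; bf = f; bdist = std::sqrt(best);
        for (int k=0;k<3;++k){ bo[k]=o[k]; bw[k]=w[k]; }
      }
    }
    out(i,0)=bo[0]; out(i,1)=bo[1]; out(i,2)=bo[2];
    bary(i,0)=bw[0]; bary(i,1)=bw[1]; bary(i,2)=bw[2];
    face[i] = bf + 1;
    dist[i] = bdist;
  }
  return List::create(_["point"] = out, _["face"] = face,
                      _["bary"] = bary, _["distance"] = dist);
}
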