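#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <queue>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Closest point on a triangle (Ericson, Real-Time Collision Detection, 5.1.5)
// region: 0,1,2 = vertices a,b,c; 3 = edge ab; 4 = edge bc; 5 = edge ca; 6 = face
// ---------------------------------------------------------------------------
static inline void closest_pt_tri(const double* p, const double* a,
                                  const double* b, const double* c,
                                  double* out, int& region) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k] = b[k]-a[k]; ac[k] = c[k]-a[k]; ap[k] = p[k]-a[k]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int k=0;k<3;++k) out[k]=a[k]; region = 0; return; }
  double bp[3]; for (int k=0;k<3;++k) bp[k] = p[k]-b[k];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int k=0;k<3;++k) out[k]=b[k]; region = 1; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k=0;k<3;++k) out[k] = a[k] + v*ab[k];
    region = 3; return;
  }
  double cp[3]; for (int k=0;k<3;++k) cp[k] = p[k]-c[k];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int k=0;k<3;++k) out[k]=c[k]; region = 2; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k=0;k<3;++k) out[k] = a[k] + w*ac[k];
    region = 5; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k=0;k<3;++k) out[k] = b[k] + w*(c[k]-b[k]);
    region = 4; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k=0;k<3;++k) out[k] = a[k] + v*ab[k] + w*ac[k];
  region = 6;
}

// Uniform-grid spatial index over triangle bounding boxes.
struct TriGrid {
  int nx, ny, nz;
  double lo[3], h[3];
  std::vector< std::vector<int> > cells;
  const NumericMatrix* V;
  const IntegerMatrix* F;

  void build(const NumericMatrix& Vm, const IntegerMatrix& Fm) {
    V = &Vm; F = &Fm;
    int nv = Vm.nrow(), nf = Fm.nrow();
    double hi[3];
    for (int k=0;k<3;++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
    for (int i=0;i<nv;++i) for (int k=0;k<3;++k) {
      if (Vm(i,k) < lo[k]) lo[k] = Vm(i,k);
      if (Vm(i,k) > hi[k]) hi[k] = Vm(i,k);
    }
    double ext[3];
    for (int k=0;k<3;++k) { ext[k] = hi[k]-lo[k]; if (ext[k] <= 0) ext[k] = 1e-9; }
    double target = std::cbrt((double)std::max(nf,1));
    int n[3];
    double maxext = std::max(ext[0], std::max(ext[1], ext[2]));
    for (int k=0;k<3;++k) {
      n[k] = (int)std::ceil(target * ext[k] / maxext);
      if (n[k] < 1) n[k] = 1;
      if (n[k] > 128) n[k] = 128;
      h[k] = ext[k] / n[k];
      if (h[k] <= 0) h[k] = 1e-9;
    }
    nx = n[0]; ny = n[1]; nz = n[2];
    cells.assign((size_t)nx*ny*nz, std::vector<int>());
    for (int f=0; f<nf; ++f) {
      double bl[3], bh[3];
      for (int k=0;k<3;++k) { bl[k] = R_PosInf; bh[k] = R_NegInf; }
      for (int j=0;j<3;++j) {
        int vi = Fm(f,j) - 1;
        for (int k=0;k<3;++k) {
          double x = Vm(vi,k);
          if (x < bl[k]) bl[k] = x;
          if (x > bh[k]) bh[k] = x;
        }
      }
      int c0[3], c1[3];
      for (int k=0;k<3;++k) {
        c0[k] = clampc((int)std::floor((bl[k]-lo[k])/h[k]), k);
        c1[k] = clampc((int)std::floor((bh[k]-lo[k])/h[k]), k);
      }
      for (int i=c0[0]; i<=c1[0]; ++i)
        for (int j=c0[1]; j<=c1[1]; ++j)
          for (int kk=c0[2]; kk<=c1[2]; ++kk)
            cells[idx(i,j,kk)].push_back(f);
    }
  }
  inline int clampc(int c, int k) const {
    int n = (k==0?nx:(k==1?ny:nz));
    if (c < 0) return 0;
    if (c >= n) return n-1;
    return c;
  }
  inline size_t idx(int i, int j, int k) const {
    return (size_t)i + (size_t)nx*((size_t)j + (size_t)ny*k);
  }

  // closest triangle to point p; returns squared distance, fills cp/tri/region
  double query(const double* p, double* cpt, int& tri, int& region) const {
    int ci = clampc((int)std::floor((p[0]-lo[0])/h[0]), 0);
    int cj = clampc((int)std::floor((p[1]-lo[1])/h[1]), 1);
    int ck = clampc((int)std::floor((p[2]-lo[2])/h[2]), 2);
    double best = R_PosInf;
    tri = -1; region = -1;
    int rmax = std::max(nx, std::max(ny, nz));
    double a[3], b[3], c[3], q[3];
    for (int r = 0; r <= rmax; ++r) {
      bool any_cell = false;
      for (int i = ci-r; i <= ci+r; ++i) {
        if (i < 0 || i >= nx) continue;
        for (int j = cj-r; j <= cj+r; ++j) {
          if (j < 0 || j >= ny) continue;
          for (int k = ck-r; k <= ck+r; ++k) {
            if (k < 0 || k >= nz) continue;
            // only the shell of the ring
            if (std::max(std::abs(i-ci), std::max(std::abs(j-cj), std::abs(k-ck))) != r) continue;
            any_cell = true;
            const std::vector<int>& lst = cells[idx(i,j,k)];
            for (size_t t = 0; t < lst.size(); ++t) {
              int f = lst[t];
              for (int m=0;m<3;++m) {
                a[m] = (*V)(((*F)(f,0)-1), m);
                b[m] = (*V)(((*F)(f,1)-1), m);
                c[m] = (*V)(((*F)(f,2)-1), m);
              }
              int reg;
              closest_pt_tri(p, a, b, c, q, reg);
              double d2 = 0;
              for (int m=0;m<3;++m) { double dd = p[m]-q[m]; d2 += dd*dd; }
              if (d2 < best) {
                best = d2; tri = f; region = reg;
                for (int m=0;m<3;++m) cpt[m] = q[m];
              }
            }
          }
        }
      }
      if (tri >= 0) {
        // lower bound on distance to any cell beyond the scanned box
        double blo[3], bhi[3], dmin2 = 0;
        blo[0] = lo[0] + (ci-r)*h[0]; bhi[0] = lo[0] + (ci+r+1)*h[0];
        blo[1] = lo[1] + (cj-r)*h[1]; bhi[1] = lo[1] + (cj+r+1)*h[1];
        blo[2] = lo[2] + (ck-r)*h[2]; bhi[2] = lo[2] + (ck+r+1)*h[2];
        double m = R_PosInf;
        for (int k=0;k<3;++k) {
          m = std::min(m, p[k]-blo[k]);
          m = std::min(m, bhi[k]-p[k]);
        }
        if (m > 0 && best <= m*m) break;
      }
      (void)any_cell;
    }
    return best;
  }
};

// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix queries, NumericMatrix V, IntegerMatrix F) {
  TriGrid grid;
  grid.build(V, F);
  int n = queries.nrow();
  NumericMatrix pts(n, 3);
  NumericVector dist(n);
  IntegerVector tri(n), region(n);
  double p[3], cpt[3];
  for (int i=0;i<n;++i) {
    p[0]=queries(i,0); p[1]=queries(i,1); p[2]=queries(i,2);
    int t, reg;
    double d2 = grid.query(p, cpt, t, reg);
    pts(i,0)=cpt[0]; pts(i,1)=cpt[1]; pts(i,2)=cpt[2];
    dist[i] = std::sqrt(d2);
    tri[i] = t + 1;
    region[i] = reg;
  }
  return List::create(_["point"]=pts, _["distance"]=dist,
                      _["triangle"]=tri, _["region"]=region);
}

// Signed distance via angle-weighted pseudonormals (Baerentzen & Aanaes).
// [[Rcpp::export]]
List cpp_signed_distance(NumericMatrix queries, NumericMatrix V, IntegerMatrix F) {
  int nv = V.nrow(), nf = F.nrow();
  // face normals (unnormalised = 2*area*unit) and unit face normals
  std::vector<double> fn(nf*3), fnu(nf*3);
  std::vector<double> vn(nv*3, 0.0);
  std::unordered_map<uint64_t, std::array<double,3> > en;
  en.reserve((size_t)nf*3);
  for (int f=0; f<nf; ++f) {
    int ia = F(f,0)-1, ib = F(f,1)-1, ic = F(f,2)-1;
    double ab[3], ac[3];
    for (int k=0;k<3;++k) { ab[k]=V(ib,k)-V(ia,k); ac[k]=V(ic,k)-V(ia,k); }
    double nx = ab[1]*ac[2]-ab[2]*ac[1];
    double ny = ab[2]*ac[0]-ab[0]*ac[2];
    double nz = ab[0]*ac[1]-ab[1]*ac[0];
    double nn = std::sqrt(nx*nx+ny*ny+nz*nz);
    fn[f*3]=nx; fn[f*3+1]=ny; fn[f*3+2]=nz;
    if (nn < 1e-300) nn = 1e-300;
    fnu[f*3]=nx/nn; fnu[f*3+1]=ny/nn; fnu[f*3+2]=nz/nn;
    // angle-weighted accumulation at each vertex
    int vid[3] = {ia, ib, ic};
    for (int j=0;j<3;++j) {
      int v0 = vid[j], v1 = vid[(j+1)%3], v2 = vid[(j+2)%3];
      double e1[3], e2[3];
      double n1=0, n2=0, dp=0;
      for (int k=0;k<3;++k) {
        e1[k] = V(v1,k)-V(v0,k); e2[k] = V(v2,k)-V(v0,k);
        n1 += e1[k]*e1[k]; n2 += e2[k]*e2[k]; dp += e1[k]*e2[k];
      }
      double cosang = dp / std::sqrt(std::max(n1*n2, 1e-300));
      if (cosang > 1) cosang = 1; if (cosang < -1) cosang = -1;
      double ang = std::acos(cosang);
      for (int k=0;k<3;++k) vn[v0*3+k] += ang * fnu[f*3+k];
    }
    // edge normals: sum of adjacent unit face normals
    int e[3][2] = {{ia,ib},{ib,ic},{ic,ia}};
    for (int j=0;j<3;++j) {
      int v0 = std::min(e[j][0], e[j][1]), v1 = std::max(e[j][0], e[j][1]);
      uint64_t key = (uint64_t)v0 * (uint64_t)nv + (uint64_t)v1;
      std::array<double,3>& acc = en[key];
      for (int k=0;k<3;++k) acc[k] += fnu[f*3+k];
    }
  }
  TriGrid grid;
  grid.build(V, F);
  int n = queries.nrow();
  NumericVector sd(n);
  NumericMatrix pts(n,3);
  IntegerVector tri(n);
  double p[3], cpt[3];
  for (int i=0;i<n;++i) {
    p[0]=queries(i,0); p[1]=queries(i,1); p[2]=queries(i,2);
    int f, reg;
    double d2 = grid.query(p, cpt, f, reg);
    double d = std::sqrt(d2);
    const double* nrm = NULL;
    double tmp[3];
    int ia = F(f,0)-1, ib = F(f,1)-1, ic = F(f,2)-1;
    if (reg == 6) {
      nrm = &fnu[f*3];
    } else if (reg <= 2) {
      int v = (reg==0? ia : (reg==1? ib : ic));
      tmp[0]=vn[v*3]; tmp[1]=vn[v*3+1]; tmp[2]=vn[v*3+2];
      nrm = tmp;
    } else {
      int v0, v1;
      if (reg == 3) { v0 = ia; v1 = ib; }
      else if (reg == 4) { v0 = ib; v1 = ic; }
      else { v0 = ic; v1 = ia; }
      int a = std::min(v0,v1), b = std::max(v0,v1);
      uint64_t key = (uint64_t)a * (uint64_t)nv + (uint64_t)b;
      std::array<double,3>& acc = en[key];
      tmp[0]=acc[0]; tmp[1]=acc[1]; tmp[2]=acc[2];
      nrm = tmp;
    }
    double s = (p[0]-cpt[0])*nrm[0] + (p[1]-cpt[1])*nrm[1] + (p[2]-cpt[2])*nrm[2];
    sd[i] = (s >= 0 ? d : -d);
    pts(i,0)=cpt[0]; pts(i,1)=cpt[1]; pts(i,2)=cpt[2];
    tri[i] = f + 1;
  }
  return List::create(_["signed_distance"]=sd, _["point"]=pts, _["triangle"]=tri);
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a scalar volume (Kuhn 6-tet cube decomposition).
// Vertices returned in 0-based voxel-index coordinates; faces 1-based.
// Triangles oriented with normals pointing away from the "inside" (> iso).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vol, IntegerVector dim, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  // nudge values equal to iso
  std::vector<double> val(vol.begin(), vol.end());
  double rng = 0;
  for (size_t i=0;i<val.size();++i) rng = std::max(rng, std::abs(val[i]));
  double eps = (rng > 0 ? rng : 1.0) * 1e-12;
  for (size_t i=0;i<val.size();++i) if (val[i] == iso) val[i] = iso + eps;
  (void)v;

  auto gidx = [&](int i, int j, int k) -> size_t {
    return (size_t)i + (size_t)nx*((size_t)j + (size_t)ny*k);
  };

  // Kuhn decomposition: all tets share diagonal c0 (0,0,0) -- c7 (1,1,1)
  static const int tets[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}
  };
  static const int corner_off[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
  };

  std::unordered_map<uint64_t,int> edge_vertex;  // key: packed sorted grid ids
  std::vector<double> verts;                      // flat xyz
  std::vector<int> faces;                         // flat 0-based triples

  auto edge_vtx = [&](size_t g1, size_t g2, double v1, double v2,
                      const int* p1, const int* p2) -> int {
    uint64_t a = std::min(g1,g2), b = std::max(g1,g2);
    uint64_t key = a * (uint64_t)(nx*(size_t)ny*nz) + b;
    std::unordered_map<uint64_t,int>::iterator it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - v1) / (v2 - v1);
    if (g1 > g2) { /* keep t relative to the order passed in */ }
    double x = p1[0] + t*(p2[0]-p1[0]);
    double y = p1[1] + t*(p2[1]-p1[1]);
    double z = p1[2] + t*(p2[2]-p1[2]);
    int id = (int)(verts.size()/3);
    verts.push_back(x); verts.push_back(y); verts.push_back(z);
    edge_vertex[key] = id;
    return id;
  };

  auto add_tri = [&](int a, int b, int c, const double* inside_pt) {
    // orient so normal points away from inside_pt
    double* A = &verts[a*3]; double* B = &verts[b*3]; double* C = &verts[c*3];
    double ab[3], ac[3], cen[3];
    for (int k=0;k<3;++k) {
      ab[k]=B[k]-A[k]; ac[k]=C[k]-A[k];
      cen[k] = (A[k]+B[k]+C[k])/3.0 - inside_pt[k];
    }
    double nxv = ab[1]*ac[2]-ab[2]*ac[1];
    double nyv = ab[2]*ac[0]-ab[0]*ac[2];
    double nzv = ab[0]*ac[1]-ab[1]*ac[0];
    double dp = nxv*cen[0]+nyv*cen[1]+nzv*cen[2];
    if (dp >= 0) { faces.push_back(a); faces.push_back(b); faces.push_back(c); }
    else         { faces.push_back(a); faces.push_back(c); faces.push_back(b); }
  };

  int cp[4][3]; size_t cg[4]; double cv[4];
  for (int k=0;k<nz-1;++k)
    for (int j=0;j<ny-1;++j)
      for (int i=0;i<nx-1;++i) {
        // quick reject: all 8 same side
        bool any_in = false, any_out = false;
        for (int c=0;c<8;++c) {
          double x = val[gidx(i+corner_off[c][0], j+corner_off[c][1], k+corner_off[c][2])];
          if (x > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t=0;t<6;++t) {
          for (int m=0;m<4;++m) {
            int c = tets[t][m];
            cp[m][0] = i+corner_off[c][0];
            cp[m][1] = j+corner_off[c][1];
            cp[m][2] = k+corner_off[c][2];
            cg[m] = gidx(cp[m][0], cp[m][1], cp[m][2]);
            cv[m] = val[cg[m]];
          }
          int in[4], nin = 0, out[4], nout = 0;
          for (int m=0;m<4;++m) {
            if (cv[m] > iso) in[nin++] = m; else out[nout++] = m;
          }
          if (nin == 0 || nin == 4) continue;
          double ip[3];  // a point strictly inside
          ip[0] = cp[in[0]][0]; ip[1] = cp[in[0]][1]; ip[2] = cp[in[0]][2];
          if (nin == 1) {
            int a = edge_vtx(cg[in[0]], cg[out[0]], cv[in[0]], cv[out[0]], cp[in[0]], cp[out[0]]);
            int b = edge_vtx(cg[in[0]], cg[out[1]], cv[in[0]], cv[out[1]], cp[in[0]], cp[out[1]]);
            int c = edge_vtx(cg[in[0]], cg[out[2]], cv[in[0]], cv[out[2]], cp[in[0]], cp[out[2]]);
            add_tri(a, b, c, ip);
          } else if (nin == 3) {
            int a = edge_vtx(cg[in[0]], cg[out[0]], cv[in[0]], cv[out[0]], cp[in[0]], cp[out[0]]);
            int b = edge_vtx(cg[in[1]], cg[out[0]], cv[in[1]], cv[out[0]], cp[in[1]], cp[out[0]]);
            int c = edge_vtx(cg[in[2]], cg[out[0]], cv[in[2]], cv[out[0]], cp[in[2]], cp[out[0]]);
            add_tri(a, b, c, ip);
          } else { // 2 in, 2 out -> quad split into two triangles
            int a = edge_vtx(cg[in[0]], cg[out[0]], cv[in[0]], cv[out[0]], cp[in[0]], cp[out[0]]);
            int b = edge_vtx(cg[in[0]], cg[out[1]], cv[in[0]], cv[out[1]], cp[in[0]], cp[out[1]]);
            int c = edge_vtx(cg[in[1]], cg[out[1]], cv[in[1]], cv[out[1]], cp[in[1]], cp[out[1]]);
            int d = edge_vtx(cg[in[1]], cg[out[0]], cv[in[1]], cv[out[0]], cp[in[1]], cp[out[0]]);
            add_tri(a, b, c, ip);
            add_tri(a, c, d, ip);
          }
        }
      }

  int nvv = (int)(verts.size()/3), nff = (int)(faces.size()/3);
  NumericMatrix Vm(nvv, 3);
  IntegerMatrix Fm(nff, 3);
  for (int i=0;i<nvv;++i) { Vm(i,0)=verts[i*3]; Vm(i,1)=verts[i*3+1]; Vm(i,2)=verts[i*3+2]; }
  for (int i=0;i<nff;++i) { Fm(i,0)=faces[i*3]+1; Fm(i,1)=faces[i*3+1]+1; Fm(i,2)=faces[i*3+2]+1; }
  return List::create(_["vertices"]=Vm, _["faces"]=Fm);
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a logical matrix (4- or 8-connectivity).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  const int dx4[4] = {1,-1,0,0},  dy4[4] = {0,0,1,-1};
  const int dx8[8] = {1,-1,0,0,1,1,-1,-1}, dy8[8] = {0,0,1,-1,1,-1,1,-1};
  const int* dx = (connectivity == 8 ? dx8 : dx4);
  const int* dy = (connectivity == 8 ? dy8 : dy4);
  int nn = (connectivity == 8 ? 8 : 4);
  for (int j=0;j<nc;++j)
    for (int i=0;i<nr;++i) {
      if (!mask(i,j) || lab(i,j)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i,j));
      lab(i,j) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back(); stack.pop_back();
        for (int d=0; d<nn; ++d) {
          int x = p.first + dx[d], y = p.second + dy[d];
          if (x < 0 || x >= nr || y < 0 || y >= nc) continue;
          if (mask(x,y) && !lab(x,y)) {
            lab(x,y) = next;
            stack.push_back(std::make_pair(x,y));
          }
        }
      }
    }
  return lab;
}

// ---------------------------------------------------------------------------
// Even-odd rasterisation of planar polygons onto a pixel grid.
// polys: list of n x 2 matrices (physical coords); grid centers at
// origin + index*spacing, indices 0..dim-1. Parity accumulated over all
// polygons (outer boundaries fill, inner boundaries cut holes).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_polygons(List polys, NumericVector origin,
                                     NumericVector spacing, IntegerVector dim) {
  int nx = dim[0], ny = dim[1];
  LogicalMatrix out(nx, ny);
  std::fill(out.begin(), out.end(), false);
  std::vector<int> parity((size_t)nx*ny, 0);
  for (int p=0; p<polys.size(); ++p) {
    NumericMatrix P = polys[p];
    int n = P.nrow();
    if (n < 3) continue;
    for (int e=0; e<n; ++e) {
      double x1 = P(e,0), y1 = P(e,1);
      double x2 = P((e+1)%n,0), y2 = P((e+1)%n,1);
      if (y1 == y2) continue;
      // pixel rows (second index) whose center y lies in [min(y1,y2), max)
      double ylo = std::min(y1,y2), yhi = std::max(y1,y2);
      int j0 = (int)std::ceil((ylo - origin[1]) / spacing[1] - 1e-12);
      int j1 = (int)std::floor((yhi - origin[1]) / spacing[1]);
      if (j0 < 0) j0 = 0;
      if (j1 > ny-1) j1 = ny-1;
      for (int j=j0; j<=j1; ++j) {
        double yc = origin[1] + j*spacing[1];
        // half-open rule: count crossing if ylo <= yc < yhi
        if (yc < ylo || yc >= yhi) continue;
        double t = (yc - y1) / (y2 - y1);
        double xint = x1 + t*(x2 - x1);
        // all pixel centers strictly left of the intersection flip parity
        int imax = (int)std::floor((xint - origin[0]) / spacing[0] - 1e-12);
        if (imax > nx-1) imax = nx-1;
        for (int i=0; i<=imax; ++i) parity[(size_t)i + (size_t)nx*j] ^= 1;
      }
    }
  }
  for (int j=0;j<ny;++j)
    for (int i=0;i<nx;++i)
      out(i,j) = parity[(size_t)i + (size_t)nx*j] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing of a 3D array, reflect boundary.
// sigma per axis in voxels; sigma <= 0 skips that axis.
// ---------------------------------------------------------------------------
static std::vector<double> gauss_kernel1d(double sigma) {
  int r = (int)std::ceil(4.0*sigma);
  std::vector<double> k(2*r+1);
  double s = 0;
  for (int i=-r;i<=r;++i) {
    k[i+r] = std::exp(-0.5*(double)i*i/(sigma*sigma));
    s += k[i+r];
  }
  for (size_t i=0;i<k.size();++i) k[i] /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth3(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  size_t sx = 1, sy = nx, sz = (size_t)nx*ny;
  int n[3] = {nx, ny, nz};
  size_t stride[3] = {sx, sy, sz};
  for (int ax=0; ax<3; ++ax) {
    if (sigma[ax] <= 0) continue;
    std::vector<double> k = gauss_kernel1d(sigma[ax]);
    int r = ((int)k.size()-1)/2;
    int len = n[ax];
    size_t st = stride[ax];
    // iterate over all lines along axis ax
    int n1 = n[(ax+1)%3], n2 = n[(ax+2)%3];
    size_t st1 = stride[(ax+1)%3], st2 = stride[(ax+2)%3];
    for (int i1=0; i1<n1; ++i1)
      for (int i2=0; i2<n2; ++i2) {
        size_t base = (size_t)i1*st1 + (size_t)i2*st2;
        for (int i=0;i<len;++i) {
          double acc = 0;
          for (int d=-r; d<=r; ++d) {
            int idx = i + d;
            // reflect (mirror without repeating the border sample beyond ends)
            while (idx < 0 || idx >= len) {
              if (idx < 0) idx = -idx;
              if (idx >= len) idx = 2*(len-1) - idx;
            }
            acc += k[d+r] * a[base + (size_t)idx*st];
          }
          b[base + (size_t)i*st] = acc;
        }
      }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}
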