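species,phase,mean,sd,letter
Aj,A,0.2,0.1,a
Aj,B,18.4,1.3,cd
Aj,C,67.5,3.4,b
Aj,D,59.4,3.1,d
Aj,E,85.4,4.2,b
Aj,F,50.2,2.6,d
Aj,G,52.2,3.2,d
Aj,H,49.1,2.3,e
Aj,I,45.7,2.2,e
Aj,J,59.0,2.9,e
Aj,K,49.1,2.5,e
Aj,L,57.3,2.7,d
Aj,M,49.6,2.4,c
Aj,N,70.7,3.6,c
Csin,A,0.2,0.1,a
Csin,B,23.6,2.0,a
Csin,C,83.3,4.1,a
Csin,D,92.8,3.8,a
Csin,E,116.6,5.1,a
Csin,F,47.9,2.4,d
Csin,G,41.9,2.5,e
Csin,H,70.2,3.1,d
Csin,I,63.2,2.8,d
Csin,J,52.9,2.6,e
Csin,K,52.4,2.7,e
Csin,L,49.4,2.3,
Csin,M,90.5,3.9,b
Csin,N,104.9,4.4,b
Qa,A,0.1,0.1,a
Qa,B,21.9,1.8,ab
Qa,C,84.1,3.6,a
Qa,D,75.2,4.0,b
Qa,E,87.9,4.7,b
Qa,F,80.4,3.9,b
Qa,G,85.3,4.4,b
Qa,H,113.4,4.9,b
Qa,I,108.6,4.5,b
Qa,J,138.8,5.3,b
Qa,K,122.0,4.9,b
Qa,L,151.1,5.8,a
Qa,M,131.0,5.5,a
Qa,N,143.0,5.4,a
Qp,A,0.3,0.2,a
Qp,B,22.9,1.6,ab
Qp,C,88.7,4.2,a
Qp,D,87.4,3.7,a
Qp,E,111.7,5.2,a
Qp,F,81.3,4.0,b
Qp,G,86.0,4.1,b
Qp,H,125.9,5.4,a
Qp,I,109.6,4.8,b
Qp,J,122.4,5.1,c
Qp,K,103.2,4.2,c
Qp,L,126.8,5.0,c
Qp,M,130.5,5.3,a
Qp,N,139.6,5.5,a
Qs,A,0.2,0.1,a
Qs,B,16.4,1.5,d
Qs,C,57.3,2.9,c
Qs,D,74.2,3.1,b
Qs,E,114.3,4.3,a
Qs,F,95.0,4.1,a
Qs,G,98.9,3.8,a
Qs,H,132.2,4.7,a
Qs,I,126.0,4.6,a
Qs,J,150.1,5.6,a
Qs,K,129.0,4.7,a
Qs,L,136.3,5.1,b
Qs,M,134.3,5.2,a
Qs,N,137.9,5.6,a
Tj,A,0.3,0.2,a
Tj,B,20.5,0.2,bc
Tj,C,60.2,0.2,c
Tj,D,66.3,0.2,c
Tj,E,70.8,0.2,c
Tj,F,59.7,0.2,c
Tj,G,65.1,0.2,c
Tj,H,88.2,0.2,c
Tj,I,80.4,0.2,c
Tj,J,82.1,0.2,d
Tj,K,66.2,0.2,d
Tj,L,52.8,0.2,de
Tj,M,45.6,0.2,c
Tj,N,38.9,0.2,d
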